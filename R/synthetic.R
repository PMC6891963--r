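# Synthetic cohort generator with planted ground truth. Emulates the
# statistical structure of the study inputs: lognormal protein lengths and
# relative abundances, Gaussian propensity z-scores, multinomial spectral
# counts per sample, four ordered contexts (HC -> DC -> AF -> RV) with a
# planted metastable subproteome whose abundance escalates toward the
# inclusion and a planted set of highly supersaturated proteins that are
# downregulated near it.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe the study conditions the generator emulates: a
#' 2000-protein proteome, five patients per context (disease contexts
#' share patients so paired comparisons are possible; healthy controls
#' are separate patients), two replicates per patient, ~10^4 spectral
#' counts per sample, a 50-protein metastable subproteome drawn from the
#' upper half of the abundance distribution whose log10 abundance rises
#' +0.2/+0.4/+0.6 in DC/AF/RV relative to HC, and a downregulated set of
#' the top 5% most supersaturated remaining proteins, decremented by 0.5
#' log10 in AF and RV.
#'
#' @param n_proteins proteome size.
#' @param n_patients named integer vector, patients per context.
#' @param n_replicates replicates per patient and context.
#' @param counts_depth total spectral counts per sample.
#' @param length_meanlog,length_sdlog lognormal protein-length parameters
#'   (natural-log scale; defaults give a median near 450 residues).
#' @param abundance_sdlog10 sd of base log10 relative abundance.
#' @param propensity_mean,propensity_sd Gaussian parameters shared by the
#'   z_agg, z_agg_sc and z_tango scores.
#' @param propensity_cor correlation between propensity scores and base
#'   log10 abundance (0 = independent).
#' @param sub_size metastable subproteome size.
#' @param sub_quantile abundance quantile above which subproteome members
#'   are drawn.
#' @param sub_increments named numeric: planted log10 abundance increments
#'   per context (relative to HC).
#' @param down_fraction fraction of (non-subproteome) proteins, ranked by
#'   true supersaturation, planted as downregulated.
#' @param down_decrement log10 abundance decrement applied to the
#'   downregulated set, per context.
#' @param biological_sd per-patient per-protein log10 abundance noise.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 2000,
                             n_patients = c(HC = 5, DC = 5, AF = 5, RV = 5),
                             n_replicates = 2,
                             counts_depth = 1e4,
                             length_meanlog = log(450),
                             length_sdlog = 0.35,
                             abundance_sdlog10 = 1,
                             propensity_mean = 0,
                             propensity_sd = 1,
                             propensity_cor = 0,
                             sub_size = 50,
                             sub_quantile = 0.5,
                             sub_increments = c(HC = 0, DC = 0.2,
                                                AF = 0.4, RV = 0.6),
                             down_fraction = 0.05,
                             down_decrement = 0.5,
                             biological_sd = 0.15) {
  n_patients <- unlist(n_patients)        # YAML configs deliver lists
  sub_increments <- unlist(sub_increments)
  stopifnot(n_proteins >= 10, sub_size < n_proteins, counts_depth >= 1,
            n_replicates >= 1, all(n_patients >= 1),
            all(names(n_patients) %in% CONTEXTS),
            all(is.finite(sub_increments)),
            down_fraction >= 0, down_fraction < 1,
            abs(propensity_cor) <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws per-protein lengths and base relative abundances, plants the
#' escalating metastable subproteome and the downregulated
#' top-supersaturated set, and emits per-context spectral-count tables:
#' for each sample, counts are multinomial with total `counts_depth` and
#' probabilities proportional to abundance x length (longer proteins
#' yield more spectra), so the NSAF-style normalization recovers relative
#' abundance exactly in expectation. Fixed seed gives bit-identical
#' output.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return list of class `synthetic_cohort`: `tables` (named list of
#'   [sample_table()] per context), `propensity` (a [propensity_table()]),
#'   `truth` (list: `subproteome` and `downregulated` [protein_set()]s,
#'   `mu` true per-context mean log10 relative abundances, `lengths`,
#'   `config`, `seed`).
#' @export
generate_cohort <- function(config = synthetic_config(), seed) {
  stopifnot(inherits(config, "synthetic_config"))
  if (missing(seed)) stop("seed is mandatory for stochastic procedures")
  set.seed(seed)
  P <- config$n_proteins
  ids <- sprintf("SP%05d", seq_len(P))
  lengths <- pmax(50L, as.integer(round(
    rlnorm(P, config$length_meanlog, config$length_sdlog))))
  a0 <- rnorm(P, 0, config$abundance_sdlog10)  # base log10 relative abundance
  draw_z <- function() {
    z <- rnorm(P, 0, 1)
    r <- config$propensity_cor
    config$propensity_mean + config$propensity_sd *
      (r * scale(a0)[, 1] + sqrt(1 - r^2) * z)
  }
  prop <- propensity_table(data.frame(
    id = ids, z_agg = draw_z(), z_agg_sc = draw_z(), z_tango = draw_z(),
    stringsAsFactors = FALSE))

  eligible <- which(a0 >= quantile(a0, config$sub_quantile))
  sub_idx <- sort(sample(eligible, config$sub_size))
  # downregulated set: most supersaturated (abundance + folded propensity)
  # among the remaining proteins
  sigma_true <- a0 + prop$z_agg_sc
  pool <- setdiff(seq_len(P), sub_idx)
  n_down <- ceiling(config$down_fraction * length(pool))
  down_idx <- pool[order(-sigma_true[pool])][seq_len(n_down)]

  contexts <- intersect(CONTEXTS, names(config$n_patients))
  mu <- matrix(a0, P, length(contexts), dimnames = list(ids, contexts))
  for (ctx in contexts) {
    inc <- config$sub_increments[[ctx]] %||% 0
    mu[sub_idx, ctx] <- mu[sub_idx, ctx] + inc
    if (ctx %in% c("AF", "RV"))
      mu[down_idx, ctx] <- mu[down_idx, ctx] - config$down_decrement
  }

  proteins <- data.frame(id = ids, length = lengths, stringsAsFactors = FALSE)
  tables <- list()
  for (ctx in contexts) {
    npat <- config$n_patients[[ctx]]
    # disease contexts share patients so paired designs are possible
    pat_ids <- if (ctx == "HC") sprintf("H%02d", seq_len(npat))
               else sprintf("P%02d", seq_len(npat))
    counts <- NULL
    meta <- NULL
    for (ip in seq_len(npat)) {
      pat_mu <- mu[, ctx] + rnorm(P, 0, config$biological_sd)
      prob <- 10^pat_mu * lengths
      for (r in seq_len(config$n_replicates)) {
        cts <- rmultinom(1, size = config$counts_depth, prob = prob)[, 1]
        counts <- cbind(counts, cts)
        meta <- rbind(meta, data.frame(
          sample_id = sprintf("%s_%s_r%d", ctx, pat_ids[ip], r),
          patient_id = pat_ids[ip], context = ctx, replicate = r,
          stringsAsFactors = FALSE))
      }
    }
    colnames(counts) <- meta$sample_id
    tables[[ctx]] <- sample_table(counts, proteins, meta)
  }

  truth <- list(
    subproteome = protein_set("planted_subproteome", ids[sub_idx]),
    downregulated = if (n_down > 0)
      protein_set("planted_downregulated", ids[down_idx]),
    mu = mu, lengths = setNames(lengths, ids),
    config = config, seed = seed)
  structure(list(tables = tables, propensity = prop, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$propensity), " proteins, contexts: ",
      paste(names(x$tables), collapse = " "), "\n  planted subproteome: ",
      length(x$truth$subproteome$members), "; downregulated: ",
      length(x$truth$downregulated$members), "\n", sep = "")
  invisible(x)
}

#' Generate synthetic expression data
#'
#' Emits microarray-like and RNA-seq-like expression inputs consistent
#' with a cohort's ground truth, so the expression-processing paths
#' (cross-tissue / skeletal-muscle averaging, FPKM averaging, two- to
#' one-tailed q conversion) can be exercised end to end. The microarray
#' matrix contains normal-tissue, skeletal-muscle, cell-line and
#' malignant arrays; the RNA-seq table carries 1-2 transcripts per
#' accession with per-transcript two-tailed q-values from a t-test of
#' simulated disease vs control replicates (the planted downregulated set
#' is decremented in disease).
#'
#' @param cohort a [generate_cohort()] result.
#' @param seed integer seed.
#' @param n_tissues number of normal-tissue arrays (besides 2 skeletal
#'   muscle, 5 cell line, 5 malignant).
#' @param tissue_sd per-array log10 expression noise.
#' @param n_reps RNA-seq replicates per group.
#' @param rnaseq_sd per-replicate log10 FPKM noise.
#' @return list: `microarray` (list `values`, `tissue_info`), `rnaseq`
#'   (data.frame for [process_rnaseq()]).
#' @export
generate_expression <- function(cohort, seed, n_tissues = 28,
                                tissue_sd = 0.3, n_reps = 5,
                                rnaseq_sd = 0.1) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (missing(seed)) stop("seed is mandatory for stochastic procedures")
  set.seed(seed)
  ids <- rownames(cohort$truth$mu)
  a0 <- cohort$truth$mu[, "HC"]
  P <- length(ids)

  n_arrays <- n_tissues + 2 + 5 + 5
  tissue_info <- data.frame(
    tissue = c(sprintf("tissue%02d", seq_len(n_tissues)),
               "skeletal_muscle_1", "skeletal_muscle_2",
               sprintf("cell_line%d", 1:5), sprintf("tumor%d", 1:5)),
    cell_line = rep(c(FALSE, FALSE, TRUE, FALSE), c(n_tissues, 2, 5, 5)),
    malignant = rep(c(FALSE, FALSE, FALSE, TRUE), c(n_tissues, 2, 5, 5)),
    skeletal_muscle = rep(c(FALSE, TRUE, FALSE, FALSE),
                          c(n_tissues, 2, 5, 5)),
    stringsAsFactors = FALSE)
  values <- 10^(matrix(a0, P, n_arrays) +
                  matrix(rnorm(P * n_arrays, 0, tissue_sd), P, n_arrays))
  rownames(values) <- ids

  n_tx <- sample(1:2, P, replace = TRUE)
  acc <- rep(ids, n_tx)
  down <- acc %in% cohort$truth$downregulated$members
  base <- rep(a0, n_tx) + rnorm(length(acc), 0, 0.1)
  shift <- ifelse(down, -cohort$truth$config$down_decrement, 0)
  ctl <- matrix(base, length(acc), n_reps) +
    matrix(rnorm(length(acc) * n_reps, 0, rnaseq_sd), length(acc))
  dis <- matrix(base + shift, length(acc), n_reps) +
    matrix(rnorm(length(acc) * n_reps, 0, rnaseq_sd), length(acc))
  pvals <- vapply(seq_along(acc), function(i)
    t.test(dis[i, ], ctl[i, ])$p.value, numeric(1))
  rnaseq <- data.frame(
    transcript = sprintf("TX%06d", seq_along(acc)),
    id = acc,
    fpkm = 10^rowMeans(ctl) * 100,   # arbitrary linear FPKM scale
    qvalue = pmin(1, bh_adjust(pvals)),
    lfc = rowMeans(dis) - rowMeans(ctl),
    stringsAsFactors = FALSE)
  list(microarray = list(values = values, tissue_info = tissue_info),
       rnaseq = rnaseq)
}
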