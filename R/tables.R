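#' @useDynLib supersat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm rmultinom rlnorm runif t.test wilcox.test
#'   fisher.test p.adjust quantile sd setNames
#' @importFrom utils read.delim write.table head
"_PACKAGE"

#' Tissue contexts, ordered from healthy to inclusion
#'
#' The four laser-microdissection contexts along the axis of escalating
#' supersaturation: healthy-control fibers (HC), unaffected fibers from
#' diseased patients (DC), affected-fiber sarcoplasm outside the vacuole
#' (AF), and the rimmed vacuole itself (RV).
#' @export
CONTEXTS <- c("HC", "DC", "AF", "RV")

#' Supersaturation score variants
#'
#' Names of the supported score variants and the propensity column each one
#' draws its Z term from: `sigma_u` and `sigma_u_ts` use the unfolded-state
#' Zyggregator score (`z_agg`), `sigma_f` the structurally corrected score
#' (`z_agg_sc`), `sigma_f_T` the TANGO score (`z_tango`), and `sigma_f_Zagg`
#' the unfolded score paired with proteomic abundances.
#' @export
SIGMA_VARIANTS <- c(
  sigma_u      = "z_agg",
  sigma_u_ts   = "z_agg",
  sigma_f      = "z_agg_sc",
  sigma_f_T    = "z_tango",
  sigma_f_Zagg = "z_agg"
)

#' Construct a spectral-count sample table
#'
#' Bundles a proteins x samples matrix of spectral counts with the protein
#' records (accession, length in residues) and per-sample metadata
#' (patient, context, replicate), validating the pieces against each other.
#'
#' @param counts non-negative integer matrix, proteins in rows, samples in
#'   columns. Row names are ignored; identities come from `proteins`.
#' @param proteins data.frame with columns `id` (unique, non-empty accession)
#'   and `length` (residues, >= 1), one row per count-matrix row.
#' @param samples data.frame with columns `sample_id`, `patient_id`,
#'   `context` (one of [CONTEXTS]) and `replicate` (integer >= 1), one row
#'   per count-matrix column.
#' @return An object of class `sample_table`: a list with elements `counts`,
#'   `proteins`, `samples`.
#' @export
sample_table <- function(counts, proteins, samples) {
  counts <- as.matrix(counts)
  proteins <- as.data.frame(proteins, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  stopifnot(is.numeric(counts))
  if (!all(c("id", "length") %in% names(proteins)))
    stop("`proteins` needs columns 'id' and 'length'")
  if (!all(c("sample_id", "patient_id", "context", "replicate") %in% names(samples)))
    stop("`samples` needs columns 'sample_id', 'patient_id', 'context', 'replicate'")
  if (nrow(counts) != nrow(proteins))
    stop("count matrix has ", nrow(counts), " rows but ", nrow(proteins),
         " protein records")
  if (ncol(counts) != nrow(samples))
    stop("count matrix has ", ncol(counts), " columns but ", nrow(samples),
         " sample records")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  if (any(!nzchar(proteins$id)) || anyDuplicated(proteins$id))
    stop("protein ids must be non-empty and unique")
  if (any(proteins$length < 1))
    stop("protein lengths must be >= 1")
  bad <- setdiff(unique(samples$context), CONTEXTS)
  if (length(bad))
    stop("unknown context label(s): ", paste(bad, collapse = ", "))
  key <- paste(samples$patient_id, samples$context, samples$replicate)
  if (anyDuplicated(key))
    stop("(patient_id, context, replicate) must be unique")
  if (anyDuplicated(samples$sample_id))
    stop("sample_id must be unique")
  if (any(colSums(counts) == 0))
    stop("every sample must have at least one positive count")
  dimnames(counts) <- list(proteins$id, samples$sample_id)
  structure(list(counts = counts, proteins = proteins, samples = samples),
            class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat("<sample_table> ", nrow(x$counts), " proteins x ", ncol(x$counts),
      " samples\n", sep = "")
  tab <- table(factor(x$samples$context, levels = CONTEXTS))
  cat("  samples per context:",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Construct an aggregation-propensity table
#'
#' Per-protein aggregation-propensity z-scores. Each score column is
#' optional per protein (NA = unavailable) but every retained protein must
#' carry at least one finite score.
#'
#' @param df data.frame with column `id` and any of `z_agg` (unfolded-state
#'   Zyggregator), `z_agg_sc` (structurally corrected), `z_tango` (TANGO).
#' @return data.frame of class `propensity_table`.
#' @export
propensity_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  score_cols <- intersect(c("z_agg", "z_agg_sc", "z_tango"), names(df))
  if (!"id" %in% names(df) || !length(score_cols))
    stop("need column 'id' and at least one of 'z_agg', 'z_agg_sc', 'z_tango'")
  if (anyDuplicated(df$id)) stop("duplicate protein ids")
  sc <- as.matrix(df[score_cols])
  if (any(is.infinite(sc))) stop("propensity scores must be finite")
  if (any(rowSums(is.finite(sc)) == 0))
    stop("every protein needs at least one propensity score")
  class(df) <- c("propensity_table", "data.frame")
  df
}

#' Construct an expression table
#'
#' Per-protein expression values on the log10 scale after processing, with
#' their provenance and (for RNA-seq) a one-tailed q-value for differential
#' expression.
#'
#' @param df data.frame with columns `id`, `value` (log10 expression),
#'   optionally `n_used` and `qvalue` (one-tailed, in (0, 1]).
#' @param provenance one of `"microarray_cross_tissue"`,
#'   `"microarray_skeletal_muscle"`, `"rnaseq"`.
#' @return data.frame of class `expression_table` with attribute `provenance`.
#' @export
expression_table <- function(df,
                             provenance = c("microarray_cross_tissue",
                                            "microarray_skeletal_muscle",
                                            "rnaseq")) {
  provenance <- match.arg(provenance)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "value") %in% names(df)))
  if (any(!is.finite(df$value))) stop("expression values must be finite")
  if (!is.null(df$qvalue)) {
    q <- df$qvalue[!is.na(df$qvalue)]
    if (any(q <= 0 | q > 1)) stop("q-values must lie in (0, 1]")
  }
  attr(df, "provenance") <- provenance
  class(df) <- c("expression_table", "data.frame")
  df
}

#' Construct a named protein set
#'
#' A named collection of protein accessions, e.g. the RV-enriched proteins
#' or plaque co-aggregators. `nominal_size` is the number of proteins that
#' met the selecting criterion, which may exceed the number present in any
#' given score table; resampling tests draw `nominal_size` proteins.
#'
#' @param name set label.
#' @param members character vector of accessions (duplicates collapsed).
#' @param nominal_size integer; defaults to the number of distinct members.
#' @return An object of class `protein_set`.
#' @export
protein_set <- function(name, members, nominal_size = NULL) {
  members <- unique(as.character(members))
  members <- members[nzchar(members)]
  if (!length(members)) stop("protein set must have at least one member")
  if (is.null(nominal_size)) nominal_size <- length(members)
  nominal_size <- as.integer(nominal_size)
  if (nominal_size < 1) stop("nominal_size must be >= 1")
  structure(list(name = as.character(name), members = members,
                 nominal_size = nominal_size),
            class = "protein_set")
}

#' @export
print.protein_set <- function(x, ...) {
  cat("<protein_set> '", x$name, "': ", length(x$members),
      " members (nominal N = ", x$nominal_size, ")\n", sep = "")
  invisible(x)
}
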