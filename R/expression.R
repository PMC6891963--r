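# Expression-derived concentration terms: cross-tissue / skeletal-muscle
# microarray averages and RNA-seq FPKM processing. Note the averaging order
# differs between platforms: microarray values are log10-transformed per
# value and then averaged; RNA-seq FPKMs are averaged on the linear scale
# and then log10-transformed. Protein abundances (abundance.R) are likewise
# mean-then-log.

#' Process microarray expression into a log10 expression table
#'
#' Cell-line and malignant-tissue arrays are excluded in cross-tissue mode;
#' skeletal-muscle mode restricts to the skeletal-muscle arrays. Values
#' <= 0 are dropped, remaining values are log10-transformed and averaged
#' per accession. Accessions with no surviving value are absent from the
#' output.
#'
#' @param values numeric matrix, accessions x arrays, rownames = accessions.
#' @param tissue_info data.frame with one row per array: columns `tissue`,
#'   logical `cell_line`, `malignant`, `skeletal_muscle`.
#' @param mode `"cross_tissue"` or `"skeletal_muscle"`.
#' @return An [expression_table()].
#' @export
process_microarray <- function(values, tissue_info,
                               mode = c("cross_tissue", "skeletal_muscle")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  stopifnot(nrow(tissue_info) == ncol(values))
  keep <- if (mode == "cross_tissue") {
    !(tissue_info$cell_line | tissue_info$malignant)
  } else {
    as.logical(tissue_info$skeletal_muscle)
  }
  if (!any(keep)) stop("no arrays retained under mode ", mode)
  v <- values[, keep, drop = FALSE]
  v[v <= 0] <- NA
  lv <- log10(v)
  n_used <- rowSums(!is.na(lv))
  mean_lv <- rowMeans(lv, na.rm = TRUE)
  pos <- n_used > 0
  expression_table(
    data.frame(id = rownames(values)[pos], value = mean_lv[pos],
               n_used = n_used[pos], stringsAsFactors = FALSE),
    provenance = if (mode == "cross_tissue") "microarray_cross_tissue"
                 else "microarray_skeletal_muscle")
}

#' Process RNA-seq FPKM values into a log10 expression table
#'
#' FPKM values <= 0 are excluded; multiple transcripts mapping to one
#' accession are averaged on the linear scale, then log10-transformed.
#' Differential-expression q-values arrive two-tailed: per accession the
#' largest transcript q is retained and converted to a one-tailed q — q/2
#' when that transcript's fold-change direction matches the tested tail,
#' 1 - q/2 otherwise.
#'
#' @param raw data.frame with columns `transcript`, `id` (accession),
#'   `fpkm`, and optionally `qvalue` (two-tailed, in (0,1]) and `lfc`
#'   (signed log fold change, disease vs control).
#' @param tail tested tail for the one-tailed conversion: `"down"`
#'   (decreased in disease) or `"up"`.
#' @return An [expression_table()] with a one-tailed `qvalue` column when
#'   q-values were supplied.
#' @export
process_rnaseq <- function(raw, tail = c("down", "up")) {
  tail <- match.arg(tail)
  raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "fpkm") %in% names(raw)))
  if (!is.null(raw$qvalue)) {
    q <- raw$qvalue[!is.na(raw$qvalue)]
    if (any(q <= 0 | q > 1)) stop("two-tailed q-values must lie in (0, 1]")
  }
  raw <- raw[is.finite(raw$fpkm) & raw$fpkm > 0, , drop = FALSE]
  if (!nrow(raw)) stop("no positive FPKM values")
  sp <- split(raw, raw$id)
  rows <- lapply(sp, function(d) {
    val <- log10(mean(d$fpkm))
    q1 <- NA_real_
    if (!is.null(d$qvalue) && any(!is.na(d$qvalue))) {
      i <- which.max(d$qvalue)              # most conservative transcript
      q2 <- d$qvalue[i]
      matches <- if (is.null(d$lfc) || is.na(d$lfc[i])) TRUE
                 else (tail == "down") == (d$lfc[i] < 0)
      q1 <- if (matches) q2 / 2 else 1 - q2 / 2
    }
    data.frame(id = d$id[1], value = val, n_used = nrow(d), qvalue = q1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  expression_table(out, provenance = "rnaseq")
}
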