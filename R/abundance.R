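# Conversion of spectral counts to the log10 relative-concentration term C.

#' Length-normalized relative abundances (NSAF-style)
#'
#' For each sample, spectral counts are divided by the sample's total
#' count, then by protein length (longer proteins yield more peptides at
#' equal molar abundance), then renormalized so the sample sums to one.
#' The result is a relative (dimensionless) abundance per protein per
#' sample.
#'
#' @param table a [sample_table()].
#' @return numeric matrix, proteins x samples; every column sums to 1.
#' @export
normalize_counts <- function(table) {
  stopifnot(inherits(table, "sample_table"))
  totals <- colSums(table$counts)
  if (any(totals == 0)) stop("sample with all-zero counts")
  norm <- sweep(table$counts, 2, totals, "/") / table$proteins$length
  sweep(norm, 2, colSums(norm), "/")
}

#' Average replicate abundances and log10-transform
#'
#' Normalized abundances are averaged across the replicate samples of one
#' context on the linear scale, then log10-transformed. Proteins whose
#' averaged abundance is zero are absent from the result (no pseudo-count
#' or -Inf imputation: a protein not seen in a context is undefined there).
#'
#' @param normalized matrix from [normalize_counts()].
#' @param samples sample metadata (`samples` element of the table).
#' @param context context label to average over.
#' @param patient optional patient id: restrict to that patient's
#'   replicates (per-patient tables feed the paired enrichment test).
#' @return data.frame of class `abundance_table` with columns `id`, `value`
#'   (log10 relative abundance) and `n_used` (replicates averaged);
#'   attribute `context`.
#' @export
average_and_log <- function(normalized, samples, context, patient = NULL) {
  keep <- samples$context == context
  if (!is.null(patient)) keep <- keep & samples$patient_id == patient
  if (!any(keep))
    stop("no samples of context ", context,
         if (!is.null(patient)) paste0(" for patient ", patient))
  sub <- normalized[, keep, drop = FALSE]
  m <- rowMeans(sub)
  pos <- m > 0
  out <- data.frame(id = rownames(normalized)[pos],
                    value = log10(m[pos]),
                    n_used = ncol(sub),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "context") <- context
  class(out) <- c("abundance_table", "data.frame")
  out
}

#' Per-context (or per-patient) log10 abundance tables
#'
#' Convenience wrapper: normalizes once and averages per requested context.
#' With `per_patient = TRUE` it returns, per context, a proteins x patients
#' matrix of log10 abundances (NA where a protein was not observed for a
#' patient), the input to the paired enrichment test.
#'
#' @param table a [sample_table()].
#' @param contexts contexts to process (default: those present).
#' @param per_patient logical.
#' @return named list per context of `abundance_table`s, or of matrices
#'   when `per_patient = TRUE`.
#' @export
abundance_by_context <- function(table, contexts = NULL, per_patient = FALSE) {
  stopifnot(inherits(table, "sample_table"))
  norm <- normalize_counts(table)
  if (is.null(contexts))
    contexts <- intersect(CONTEXTS, unique(table$samples$context))
  out <- lapply(contexts, function(ctx) {
    if (!per_patient) return(average_and_log(norm, table$samples, ctx))
    pats <- unique(table$samples$patient_id[table$samples$context == ctx])
    mat <- matrix(NA_real_, nrow(norm), length(pats),
                  dimnames = list(rownames(norm), pats))
    for (p in pats) {
      ab <- average_and_log(norm, table$samples, ctx, patient = p)
      mat[ab$id, p] <- ab$value
    }
    mat
  })
  names(out) <- contexts
  out
}
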