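# Supersaturation scores: sigma = C + Z, recentered so the proteome median
# of each table (one per context and variant) is zero. On this scale the
# median fold change of a protein set over the proteome is Delta =
# 10^median(sigma over the set).

#' Assemble a supersaturation table
#'
#' Combines a log10 concentration source (protein abundance or expression
#' table) with an aggregation-propensity table into per-protein
#' supersaturation scores sigma = C + Z. Only proteins carrying both terms
#' are retained; scores are recentered so the table median is exactly 0
#' (the recentering offset is recorded). The `variant` selects the Z
#' column per [SIGMA_VARIANTS].
#'
#' @param C_source an `abundance_table` or [expression_table()]: columns
#'   `id`, `value`.
#' @param Z_source a [propensity_table()].
#' @param variant one of `names(SIGMA_VARIANTS)`.
#' @param context label stored with the table (defaults to the abundance
#'   table's context attribute, else `"NA"`).
#' @return data.frame of class `supersaturation_table` with columns `id`,
#'   `C`, `Z`, `sigma`; attributes `variant`, `context`, `offset`.
#' @export
compute_sigma <- function(C_source, Z_source, variant = "sigma_f",
                          context = NULL) {
  if (!variant %in% names(SIGMA_VARIANTS))
    stop("unknown variant '", variant, "'")
  zcol <- SIGMA_VARIANTS[[variant]]
  if (!zcol %in% names(Z_source))
    stop("propensity table lacks column '", zcol, "' needed for ", variant)
  if (is.null(context))
    context <- attr(C_source, "context") %||% "NA"
  z <- Z_source[[zcol]]
  names(z) <- Z_source$id
  z <- z[is.finite(z)]
  common <- intersect(C_source$id, names(z))
  if (length(common) < 2)
    stop("fewer than 2 proteins have both a concentration and a ", zcol,
         " score")
  C <- C_source$value[match(common, C_source$id)]
  Z <- unname(z[common])
  raw <- C + Z
  offset <- median(raw)
  out <- data.frame(id = common, C = C, Z = Z, sigma = raw - offset,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "variant") <- variant
  attr(out, "context") <- context
  attr(out, "offset") <- offset
  class(out) <- c("supersaturation_table", "data.frame")
  out
}

#' @export
print.supersaturation_table <- function(x, ...) {
  cat("<supersaturation_table> ", attr(x, "variant"), ", context ",
      attr(x, "context"), ": ", nrow(x), " proteins (recentering offset ",
      signif(attr(x, "offset"), 4), ")\n", sep = "")
  print(head(as.data.frame(x)), ...)
  invisible(x)
}

#' Median fold change of a protein set over the proteome
#'
#' With the proteome median recentered to 0, Delta = 10^median(sigma) over
#' the set members present in the table. The nominal set size is reported
#' alongside the number of members actually present.
#'
#' @param table a [compute_sigma()] table.
#' @param subset a [protein_set()].
#' @return one-row data.frame: `set_name`, `context`, `variant`, `delta`,
#'   `median_sigma`, `n_set` (nominal), `n_used`, `n_proteome`.
#' @export
median_fold_change <- function(table, subset) {
  stopifnot(inherits(table, "supersaturation_table"),
            inherits(subset, "protein_set"))
  present <- table$sigma[table$id %in% subset$members]
  if (!length(present))
    stop("no member of '", subset$name, "' present in the table")
  ms <- median(present)
  data.frame(set_name = subset$name,
             context = attr(table, "context"),
             variant = attr(table, "variant"),
             delta = 10^ms,
             median_sigma = ms,
             n_set = subset$nominal_size,
             n_used = length(present),
             n_proteome = nrow(table),
             stringsAsFactors = FALSE)
}

#' Top supersaturated proteins
#'
#' The ceiling(fraction * n) highest-sigma proteins of the table, after an
#' optional restriction to a protein set. Boundary ties are broken by
#' accession lexicographic order so the selection is deterministic.
#'
#' @param table a [compute_sigma()] table.
#' @param fraction fraction in (0, 1), e.g. 0.05 for the top 5%.
#' @param restriction optional [protein_set()] restricting the candidate
#'   pool (the ranking universe) before the fraction is applied.
#' @return A [protein_set()] named `"top_<fraction>_<variant>"`.
#' @export
top_supersaturated <- function(table, fraction, restriction = NULL) {
  stopifnot(inherits(table, "supersaturation_table"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must lie in (0, 1)")
  df <- as.data.frame(table)
  if (!is.null(restriction)) {
    stopifnot(inherits(restriction, "protein_set"))
    df <- df[df$id %in% restriction$members, , drop = FALSE]
  }
  if (!nrow(df)) stop("empty table after restriction")
  k <- ceiling(fraction * nrow(df))
  ord <- order(-df$sigma, df$id)
  protein_set(sprintf("top_%g_%s", fraction, attr(table, "variant")),
              df$id[ord[seq_len(k)]])
}

#' Supersaturation tables for every context of a cohort
#'
#' Convenience wrapper running the count-to-score pipeline per context:
#' NSAF-style normalization, replicate averaging, log10 transform, then
#' sigma assembly and recentering against one propensity table.
#'
#' @param tables named list of [sample_table()]s (one per context).
#' @param propensity a [propensity_table()].
#' @param variant score variant, see [SIGMA_VARIANTS].
#' @return named list of [compute_sigma()] tables.
#' @export
sigma_by_context <- function(tables, propensity, variant = "sigma_f") {
  out <- lapply(names(tables), function(ctx) {
    ab <- abundance_by_context(tables[[ctx]], contexts = ctx)[[ctx]]
    compute_sigma(ab, propensity, variant = variant, context = ctx)
  })
  names(out) <- names(tables)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
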