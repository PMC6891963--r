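# Subset-vs-proteome hypothesis tests and the family-structured
# multiple-testing scheme. Every reported p-value belongs to exactly one
# family; correction within a family is Holm-Bonferroni (step-down).

#' One-tailed Wilcoxon/Mann-Whitney test
#'
#' Tests the alternative that `subset_values` are stochastically greater
#' than `proteome_values`. The exact distribution is used for small
#' tie-free samples (combined n <= 40); otherwise the normal approximation
#' with tie correction and, by default, continuity correction.
#'
#' @param subset_values,proteome_values numeric vectors.
#' @param exact force exact (`TRUE`) or approximate (`FALSE`) computation;
#'   `NULL` (default) switches at combined n = 40 and falls back to the
#'   approximation when ties are present.
#' @param correct continuity correction for the normal approximation.
#' @return one-tailed p-value.
#' @export
mannwhitney_one_tailed <- function(subset_values, proteome_values,
                                   exact = NULL, correct = TRUE) {
  x <- subset_values[is.finite(subset_values)]
  y <- proteome_values[is.finite(proteome_values)]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical across both groups; p = 0.5")
    return(0.5)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact)) exact <- (length(x) + length(y) <= 40) && !ties
  if (exact && !ties)
    return(suppressWarnings(
      wilcox.test(x, y, alternative = "greater", exact = TRUE)$p.value))
  mw_approx_greater(x, y, correct = correct)
}

# normal approximation with tie correction (and optional continuity
# correction), the same formula wilcox.test uses; computed directly
# because the noise curves call it tens of thousands of times
mw_approx_greater <- function(x, y, correct = TRUE) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  z <- U - n1 * n2 / 2
  nties <- table(r)
  sigma <- sqrt((n1 * n2 / 12) *
                  ((n1 + n2 + 1) -
                     sum(nties^3 - nties) / ((n1 + n2) * (n1 + n2 - 1))))
  if (sigma == 0) return(0.5)
  z <- (z - if (correct) 0.5 else 0) / sigma
  stats::pnorm(z, lower.tail = FALSE)
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param p named numeric vector of raw p-values (one family).
#' @return named vector of adjusted p-values, capped at 1, order preserved.
#' @export
holm_bonferroni <- function(p) {
  if (!length(p)) stop("empty family")
  stopifnot(all(p > 0 & p <= 1))
  out <- p.adjust(p, method = "holm")
  names(out) <- names(p)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of raw p-values.
#' @return q-values (FDR-adjusted p), order preserved.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) stop("empty p-vector")
  p.adjust(p, method = "BH")
}

#' Run a panel of subset-vs-proteome comparisons
#'
#' For each requested (table, subset) pair, computes the median fold
#' change Delta and the one-tailed Mann-Whitney p of the subset's sigma
#' scores against the full proteome's, then applies Holm-Bonferroni
#' within each declared family. This is the machinery behind the
#' box-plot panels and the statistical summary table.
#'
#' @param tables named list of [compute_sigma()] tables.
#' @param subsets named list of [protein_set()]s.
#' @param panel data.frame with columns `test_id`, `table`, `subset`,
#'   `family` (names into `tables`/`subsets`).
#' @return data.frame: one row per test with `delta`, `p_raw`,
#'   `p_adjusted`, `family` and the bookkeeping columns of
#'   [median_fold_change()].
#' @export
run_panel <- function(tables, subsets, panel) {
  panel <- as.data.frame(panel, stringsAsFactors = FALSE)
  need <- c("test_id", "table", "subset", "family")
  stopifnot(all(need %in% names(panel)))
  if (anyDuplicated(panel$test_id))
    stop("test id assigned to more than one family (duplicate test_id)")
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    tab <- tables[[panel$table[i]]]
    set <- subsets[[panel$subset[i]]]
    if (is.null(tab)) stop("unknown table '", panel$table[i], "'")
    if (is.null(set)) stop("unknown subset '", panel$subset[i], "'")
    fc <- median_fold_change(tab, set)
    sel <- tab$id %in% set$members
    fc$p_raw <- mannwhitney_one_tailed(tab$sigma[sel], tab$sigma)
    fc$test_id <- panel$test_id[i]
    fc$family <- panel$family[i]
    fc
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  for (f in unique(out$family)) {
    idx <- out$family == f
    out$p_adjusted[idx] <- holm_bonferroni(
      setNames(out$p_raw[idx], out$test_id[idx]))
  }
  out[c("test_id", "family", "set_name", "context", "variant", "delta",
        "median_sigma", "p_raw", "p_adjusted", "n_set", "n_used",
        "n_proteome")]
}
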