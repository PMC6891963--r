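# Bespoke resampling significance procedures: the escalating-supersaturation
# ordering null and the comparative median-Delta null. Both draw random
# protein sets of the nominal size N from the proteome universe (the union
# of proteins appearing in any participating table, matching the inclusion
# of proteins expressed in some contexts but not others) and ask how often
# chance reproduces the observed pattern.

sigma_matrix <- function(tables) {
  universe <- sort(unique(unlist(lapply(tables, `[[`, "id"))))
  m <- matrix(NA_real_, length(universe), length(tables),
              dimnames = list(universe, names(tables)))
  for (j in seq_along(tables))
    m[tables[[j]]$id, j] <- tables[[j]]$sigma
  m
}

observed_medians <- function(m, members) {
  rows <- intersect(rownames(m), members)
  vapply(seq_len(ncol(m)), function(j) {
    v <- m[rows, j]
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else median(v)
  }, numeric(1))
}

check_zero_context <- function(zero_ctx, contexts, K) {
  frac <- zero_ctx / K
  bad <- frac > 0.01
  if (any(bad))
    stop("context(s) ", paste(contexts[bad], collapse = ", "),
         " had no sampled protein present in > 1% of trials (",
         paste(sprintf("%.1f%%", 100 * frac[bad]), collapse = ", "),
         "); universe too sparse for N")
  invisible(frac)
}

#' Monte-Carlo test for escalating supersaturation
#'
#' Scores whether a protein set's median fold change Delta is positive in
#' every context and rises strictly along the ordered contexts (HC -> DC
#' -> AF -> RV), against random protein sets. Per trial, N =
#' `subset$nominal_size` proteins are drawn without replacement from the
#' universe of proteins present in any context table; the trial scores
#' E_k = 1 when its context medians satisfy the criterion (`"strict"`:
#' min > 0 and strictly increasing; `"relaxed"`: strictly increasing
#' only). The chance probability of the pattern is p_null = sum(E_k)/K.
#' The reported p-value equals p_null when the observed set itself
#' achieves the pattern and 1 otherwise (the null cannot be rejected by a
#' set that does not show the pattern).
#'
#' @param tables named list of [compute_sigma()] tables in escalation
#'   order, e.g. `list(HC=, DC=, AF=, RV=)`.
#' @param subset a [protein_set()].
#' @param K number of Monte-Carlo trials.
#' @param criterion `"strict"` or `"relaxed"`.
#' @param seed integer seed (mandatory: results are bit-reproducible).
#' @return object of class `escalation_result`: list with `D` (observed
#'   per-context median Delta, linear scale), `median_sigma` (log10),
#'   `pattern_observed`, `p_null`, `p`, `at_floor` (TRUE when no trial
#'   achieved the pattern and p_null is reported at its 1/K floor),
#'   `exceed`, `K`, `criterion`, `N`, `universe_size`,
#'   `zero_context_fraction`, `seed`.
#' @export
escalation_test <- function(tables, subset, K = 1e6,
                            criterion = c("strict", "relaxed"),
                            seed) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(subset, "protein_set"), length(tables) >= 2)
  if (missing(seed)) stop("seed is mandatory for stochastic procedures")
  K <- as.integer(K)
  m <- sigma_matrix(tables)
  N <- subset$nominal_size
  if (N > nrow(m)) stop("nominal size exceeds the proteome universe")
  obs <- observed_medians(m, subset$members)
  increasing <- !anyNA(obs) && all(diff(obs) > 0)
  pattern <- if (criterion == "strict") increasing && min(obs) > 0
             else increasing
  set.seed(seed)
  mc <- .mc_escalation(m, N, K)
  zf <- check_zero_context(mc$zero_context_trials, names(tables), K)
  exceed <- if (criterion == "strict") mc$exceed_strict else mc$exceed_relaxed
  at_floor <- exceed == 0
  p_null <- max(exceed, 1) / K
  structure(list(D = 10^obs, median_sigma = obs,
                 pattern_observed = pattern,
                 p_null = p_null, p = if (pattern) p_null else 1,
                 at_floor = at_floor, exceed = exceed, K = K,
                 criterion = criterion, N = N, universe_size = nrow(m),
                 zero_context_fraction = zf, seed = seed,
                 contexts = names(tables), set_name = subset$name),
            class = "escalation_result")
}

#' @export
print.escalation_result <- function(x, ...) {
  cat("<escalation_result> set '", x$set_name, "' (N = ", x$N,
      "), criterion ", x$criterion, "\n", sep = "")
  cat("  median Delta per context: ",
      paste(x$contexts, signif(x$D, 3), sep = "=", collapse = " "), "\n",
      sep = "")
  cat("  pattern observed: ", x$pattern_observed,
      "; chance probability p_null ", if (x$at_floor) "< " else "= ",
      signif(x$p_null, 3), " (K = ", x$K, ")\n", sep = "")
  cat("  reported p = ", signif(x$p, 3), "\n", sep = "")
  invisible(x)
}

#' Monte-Carlo test for a difference in median Delta between contexts
#'
#' One-tailed: the null hypothesis is that a difference in median Delta of
#' at least the observed magnitude (context 2 minus context 1, log scale)
#' would arise by chance for a random protein set of the same nominal
#' size. Per trial, dd_k = medDelta_2 - medDelta_1 over the sampled
#' proteins present in each table; p = (#{dd_k > dd_0})/K.
#'
#' @param table_1,table_2 [compute_sigma()] tables (context 1 and 2).
#' @param subset a [protein_set()].
#' @param K trials.
#' @param seed integer seed.
#' @return object of class `comparative_delta_result`: `dd_observed` (log10
#'   scale), `delta_1`, `delta_2` (linear), `p`, `at_floor`, `exceed`,
#'   `K`, `N`, `universe_size`, `seed`.
#' @export
comparative_delta_test <- function(table_1, table_2, subset, K = 1e6, seed) {
  stopifnot(inherits(subset, "protein_set"))
  if (missing(seed)) stop("seed is mandatory for stochastic procedures")
  K <- as.integer(K)
  tables <- list(c1 = table_1, c2 = table_2)
  m <- sigma_matrix(tables)
  N <- subset$nominal_size
  if (N > nrow(m)) stop("nominal size exceeds the proteome universe")
  obs <- observed_medians(m, subset$members)
  if (anyNA(obs)) stop("subset absent from one of the tables")
  dd0 <- obs[2] - obs[1]
  set.seed(seed)
  mc <- .mc_comparative(m, N, K, dd0)
  zf <- check_zero_context(mc$zero_context_trials, c("table_1", "table_2"), K)
  at_floor <- mc$exceed == 0
  p <- max(mc$exceed, 1) / K
  structure(list(dd_observed = dd0, delta_1 = 10^obs[1], delta_2 = 10^obs[2],
                 p = p, at_floor = at_floor, exceed = mc$exceed, K = K,
                 N = N, universe_size = nrow(m),
                 zero_context_fraction = zf, seed = seed,
                 set_name = subset$name),
            class = "comparative_delta_result")
}

#' @export
print.comparative_delta_result <- function(x, ...) {
  cat("<comparative_delta_result> set '", x$set_name, "' (N = ", x$N,
      ")\n  Delta: ", signif(x$delta_1, 3), " -> ", signif(x$delta_2, 3),
      " (difference ", signif(x$dd_observed, 3), " log10)\n  p ",
      if (x$at_floor) "< " else "= ", signif(x$p, 3), " (K = ", x$K,
      ")\n", sep = "")
  invisible(x)
}
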