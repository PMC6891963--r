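# Inclusion-enrichment and differential-abundance calls, and Fisher
# overlap enrichment between protein categories.

paired_t_one_tailed <- function(target, reference) {
  # one-tailed paired t on log10 abundances; alternative: target > reference
  d <- target - reference
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 2) return(c(diff = NA_real_, p = NA_real_, n = n))
  if (sd(d) == 0) {
    # all differences identical: t undefined; sign decides the tail
    warning("zero-variance differences; p set by sign of the difference")
    p <- if (d[1] > 0) 0 else 1
    return(c(diff = mean(d), p = p, n = n))
  }
  c(diff = mean(d),
    p = t.test(d, alternative = "greater")$p.value,
    n = n)
}

welch_t_one_tailed <- function(target, reference) {
  x <- target[is.finite(target)]
  y <- reference[is.finite(reference)]
  if (length(x) < 2 || length(y) < 2)
    return(c(diff = NA_real_, p = NA_real_, n = length(x) + length(y)))
  if (sd(x) == 0 && sd(y) == 0) {
    warning("zero-variance groups; p set by sign of the difference")
    p <- if (mean(x) > mean(y)) 0 else 1
    return(c(diff = mean(x) - mean(y), p = p, n = length(x) + length(y)))
  }
  c(diff = mean(x) - mean(y),
    p = t.test(x, y, alternative = "greater", var.equal = FALSE)$p.value,
    n = length(x) + length(y))
}

#' Identify proteins enriched in a target context
#'
#' Patient-matched comparison (e.g. rimmed vacuole vs disease-control
#' fibers): per protein, patients contribute a pair only when the protein
#' has a defined (non-zero) abundance in both conditions; proteins with
#' fewer than two pairs are dropped. A one-tailed paired t-test (target >
#' reference) is run per protein and Benjamini-Hochberg q-values computed
#' over all tested proteins; `enriched` flags q < 0.05 (FDR 5%).
#'
#' @param target,reference numeric matrices of per-patient log10
#'   abundances (proteins x patients, NA = absent), with matching patient
#'   columns.
#' @return data.frame of class `enrichment_result`: `id`, `mean_diff`,
#'   `p`, `q`, `enriched`, `n_pairs`; attribute `n_tested`.
#' @export
identify_enriched <- function(target, reference) {
  stopifnot(is.matrix(target), is.matrix(reference))
  common_p <- intersect(colnames(target), colnames(reference))
  if (length(common_p) < 3) stop("need >= 3 matched patients")
  common_i <- intersect(rownames(target), rownames(reference))
  tg <- target[common_i, common_p, drop = FALSE]
  rf <- reference[common_i, common_p, drop = FALSE]
  res <- t(vapply(seq_along(common_i),
                  function(i) paired_t_one_tailed(tg[i, ], rf[i, ]),
                  c(diff = 0, p = 0, n = 0)))
  keep <- !is.na(res[, "p"])
  if (!any(keep)) stop("no testable proteins (need >= 2 complete pairs)")
  out <- data.frame(id = common_i[keep],
                    mean_diff = res[keep, "diff"],
                    p = res[keep, "p"],
                    n_pairs = as.integer(res[keep, "n"]),
                    stringsAsFactors = FALSE)
  out$q <- bh_adjust(out$p)
  out$enriched <- out$q < 0.05
  rownames(out) <- NULL
  attr(out, "n_tested") <- nrow(out)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Identify up- and down-regulated proteins between two contexts
#'
#' Runs the enrichment machinery one-tailed in each direction, with
#' Benjamini-Hochberg correction per direction, and returns the
#' significant sets. When the two contexts come from the same patients
#' (e.g. RV vs DC) the paired t-test is used; across different patients
#' (e.g. AF vs HC) an unpaired one-tailed Welch t-test.
#'
#' @param condition,control numeric matrices of per-patient log10
#'   abundances (proteins x patients, NA = absent).
#' @param paired logical; patient-matched columns or independent cohorts.
#' @param alpha FDR threshold (default 0.05).
#' @return list with [protein_set()]s `up` and `down` (NULL when empty)
#'   and the per-direction result tables (`up_table`, `down_table`).
#' @export
identify_regulated <- function(condition, control, paired = TRUE,
                               alpha = 0.05) {
  one_direction <- function(a, b) {
    if (paired) return(identify_enriched(a, b))
    common_i <- intersect(rownames(a), rownames(b))
    res <- t(vapply(common_i,
                    function(i) welch_t_one_tailed(a[i, ], b[i, ]),
                    c(diff = 0, p = 0, n = 0)))
    keep <- !is.na(res[, "p"])
    if (!any(keep)) stop("no testable proteins")
    out <- data.frame(id = common_i[keep], mean_diff = res[keep, "diff"],
                      p = res[keep, "p"], n_pairs = as.integer(res[keep, "n"]),
                      stringsAsFactors = FALSE)
    out$q <- bh_adjust(out$p)
    out$enriched <- out$q < alpha
    rownames(out) <- NULL
    out
  }
  up <- one_direction(condition, control)
  down <- one_direction(control, condition)
  mk <- function(tab, nm) {
    ids <- tab$id[tab$q < alpha]
    if (length(ids)) protein_set(nm, ids) else NULL
  }
  list(up = mk(up, "up"), down = mk(down, "down"),
       up_table = up, down_table = down)
}

#' Fisher overlap enrichment of a category within a subset
#'
#' One-tailed (greater) Fisher exact test asking whether `subset` is
#' enriched for members of `category`, against `background`. The default
#' 2x2 construction contrasts the subset with the background excluding the
#' subset (disjoint rows); `mode = "whole"` contrasts it with the whole
#' background.
#'
#' @param category,subset,background [protein_set()]s; `subset` and
#'   `category` must be contained in `background`.
#' @param mode `"disjoint"` (default) or `"whole"`.
#' @return list: `p` (one-tailed Fisher), `fold_enrichment` (category rate
#'   in subset over its rate in background), `table` (the 2x2 matrix),
#'   `k` (category members in subset).
#' @export
overlap_enrichment <- function(category, subset, background,
                               mode = c("disjoint", "whole")) {
  mode <- match.arg(mode)
  stopifnot(inherits(category, "protein_set"),
            inherits(subset, "protein_set"),
            inherits(background, "protein_set"))
  if (!all(subset$members %in% background$members))
    stop("subset must be contained in background")
  if (!all(category$members %in% background$members))
    stop("category must be contained in background")
  bg <- background$members
  sub <- subset$members
  cat_bg <- intersect(category$members, bg)
  k <- length(intersect(cat_bg, sub))
  other <- if (mode == "disjoint") setdiff(bg, sub) else bg
  k_other <- length(intersect(cat_bg, other))
  tab <- matrix(c(k, length(sub) - k,
                  k_other, length(other) - k_other),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("subset", "rest"),
                                c("in_category", "not")))
  p <- fisher.test(tab, alternative = "greater")$p.value
  fe <- (k / length(sub)) / (length(cat_bg) / length(bg))
  list(p = p, fold_enrichment = fe, table = tab, k = k)
}
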