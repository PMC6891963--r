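# Gaussian-noise robustness testing. Noise is added to supersaturation
# scores on the log10 scale at 100 increasing standard deviations; at each
# level, 100 trials re-run the subset-vs-proteome comparison to see where
# significance and fold change break down.

#' Gaussian noise grid
#'
#' 100 noise levels: standard deviations (log10 units) linearly spaced
#' from log10(1.1) to log10(10.1), 100 trials per level.
#'
#' @param n_levels,n_trials grid dimensions (defaults 100 x 100).
#' @param sd_range endpoints of the sd range, log10 units.
#' @return data.frame of class `noise_grid` with columns `level`, `sd`;
#'   attribute `n_trials`.
#' @export
noise_grid <- function(n_levels = 100, n_trials = 100,
                       sd_range = c(log10(1.1), log10(10.1))) {
  stopifnot(n_levels >= 1, n_trials >= 1, diff(sd_range) > 0)
  g <- data.frame(level = seq_len(n_levels),
                  sd = seq(sd_range[1], sd_range[2], length.out = n_levels))
  attr(g, "n_trials") <- as.integer(n_trials)
  class(g) <- c("noise_grid", "data.frame")
  g
}

#' Perturb supersaturation scores with Gaussian noise
#'
#' Adds one independent mean-zero Gaussian draw per protein (log10 units)
#' to the scores.
#'
#' @param sigma numeric vector of scores.
#' @param level noise standard deviation (> 0), log10 units.
#' @return list: `sigma` (perturbed scores), `draws` (the noise values).
#' @export
perturb <- function(sigma, level) {
  stopifnot(level > 0)
  n <- rnorm(length(sigma), 0, level)
  list(sigma = sigma + n, draws = n)
}

#' Median linear noise magnitude across trials
#'
#' Each draw's linear magnitude is m = 10^|n| (>= 1); per trial the median
#' magnitude over proteins is taken, and the set M of per-trial medians is
#' summarized by its median (the x-axis value of a robustness curve) and
#' the standard error of its mean.
#'
#' @param draws list of numeric vectors, one per trial (the `draws` of
#'   [perturb()]).
#' @return list: `M` (per-trial median magnitudes), `median` and `sem`.
#' @export
median_noise_magnitude <- function(draws) {
  stopifnot(length(draws) >= 1)
  M <- vapply(draws, function(n) median(10^abs(n)), numeric(1))
  list(M = M, median = median(M), sem = sem(M))
}

sem <- function(x) if (length(x) < 2) NA_real_ else sd(x) / sqrt(length(x))

# shared trial loop: returns per-level lists of p / d / noise magnitudes;
# the Mann-Whitney p is skipped when only fold changes are needed
noise_trials <- function(control, experiment, grid, seed, family_size = 1,
                         compute_p = TRUE) {
  n_trials <- attr(grid, "n_trials")
  n_c <- length(control); n_e <- length(experiment)
  set.seed(seed)
  lapply(seq_len(nrow(grid)), function(l) {
    lev <- grid$sd[l]
    p <- d <- M <- numeric(n_trials)
    for (t in seq_len(n_trials)) {
      # one draw per protein in the database (control set = proteome,
      # experiment subset included), split across the two sets
      nz <- rnorm(n_c + n_e, 0, lev)
      ctl <- control + nz[seq_len(n_c)]
      expv <- experiment + nz[n_c + seq_len(n_e)]
      if (compute_p)
        p[t] <- min(1, family_size *
                      mannwhitney_one_tailed(expv, ctl, exact = FALSE))
      d[t] <- 10^(median(expv) - median(ctl))
      M[t] <- median(10^abs(nz))  # per-trial median linear noise magnitude
    }
    list(p = p, d = d, M = M)
  })
}

flag_mean_below <- function(x, threshold) {
  # one-sided one-sample t-test: is mean(x) significantly < threshold?
  if (sd(x) == 0) return(mean(x) < threshold)
  t.test(x, mu = threshold, alternative = "less")$p.value < 0.05
}

flag_mean_above <- function(x, threshold) {
  if (sd(x) == 0) return(mean(x) > threshold)
  t.test(x, mu = threshold, alternative = "greater")$p.value < 0.05
}

#' Noise-robustness curve for significance
#'
#' At each noise level, both value sets are perturbed and the one-tailed
#' Mann-Whitney test re-run for each trial (Bonferroni-scaled by the
#' size of the test's correction family, mirroring the correction applied
#' to the unperturbed analysis). A level is flagged significant
#' ("colored") when a one-sided one-sample t-test rejects the hypothesis
#' that the mean trial p-value is not below 0.05.
#'
#' @param control proteome sigma values.
#' @param experiment subset sigma values.
#' @param grid a [noise_grid()].
#' @param seed integer seed.
#' @param family_size size of the Holm family the original comparison
#'   belonged to (per-trial p-values are scaled by it; default 1).
#' @return data.frame of class `noise_curve`: per level `sd`,
#'   `noise_magnitude` (median M), `noise_magnitude_sem`, `median_p`,
#'   `sem_p`, `significant`.
#' @export
noise_significance_curve <- function(control, experiment, grid = noise_grid(),
                                     seed, family_size = 1) {
  if (missing(seed)) stop("seed is mandatory for stochastic procedures")
  trials <- noise_trials(control, experiment, grid, seed, family_size)
  out <- do.call(rbind, lapply(seq_along(trials), function(l) {
    tr <- trials[[l]]
    data.frame(level = grid$level[l], sd = grid$sd[l],
               noise_magnitude = median(tr$M), noise_magnitude_sem = sem(tr$M),
               median_p = median(tr$p), sem_p = sem(tr$p),
               significant = flag_mean_below(tr$p, 0.05))
  }))
  class(out) <- c("noise_curve", "data.frame")
  attr(out, "statistic") <- "p"
  out
}

#' Noise-robustness curve for fold change
#'
#' As [noise_significance_curve()], but tracking the linear fold change
#' d = 10^(median(experiment) - median(control)) per trial; a level is
#' flagged when a one-sided one-sample t-test rejects the hypothesis that
#' the mean trial fold change is not above 1.
#'
#' @inheritParams noise_significance_curve
#' @return data.frame of class `noise_curve`: per level `sd`,
#'   `noise_magnitude`, `noise_magnitude_sem`, `median_d`, `sem_d`,
#'   `significant`.
#' @export
noise_fold_change_curve <- function(control, experiment, grid = noise_grid(),
                                    seed) {
  if (missing(seed)) stop("seed is mandatory for stochastic procedures")
  trials <- noise_trials(control, experiment, grid, seed, compute_p = FALSE)
  out <- do.call(rbind, lapply(seq_along(trials), function(l) {
    tr <- trials[[l]]
    data.frame(level = grid$level[l], sd = grid$sd[l],
               noise_magnitude = median(tr$M), noise_magnitude_sem = sem(tr$M),
               median_d = median(tr$d), sem_d = sem(tr$d),
               significant = flag_mean_above(tr$d, 1))
  }))
  class(out) <- c("noise_curve", "data.frame")
  attr(out, "statistic") <- "d"
  out
}
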