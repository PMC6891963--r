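# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

# bare supersaturation table from a sigma vector (C/Z split is irrelevant
# for tests that only exercise sigma-level machinery)
make_sigma_table <- function(sigma, ids = sprintf("SP%05d", seq_along(sigma)),
                             context = "HC", variant = "sigma_f",
                             recenter = TRUE) {
  if (recenter) sigma <- sigma - median(sigma)
  df <- data.frame(id = ids, C = sigma, Z = 0, sigma = sigma,
                   stringsAsFactors = FALSE)
  attr(df, "variant") <- variant
  attr(df, "context") <- context
  attr(df, "offset") <- 0
  class(df) <- c("supersaturation_table", "data.frame")
  df
}

# small sample_table built by hand
make_sample_table <- function(counts, lengths,
                              contexts = rep("HC", ncol(counts)),
                              patients = paste0("p", seq_len(ncol(counts))),
                              replicates = rep(1L, ncol(counts))) {
  n <- nrow(counts)
  sample_table(counts,
               proteins = data.frame(id = sprintf("P%03d", seq_len(n)),
                                     length = lengths),
               samples = data.frame(
                 sample_id = paste0("s", seq_len(ncol(counts))),
                 patient_id = patients, context = contexts,
                 replicate = replicates))
}

# scaled-down cohort for fast end-to-end tests
small_cohort <- function(seed, ...) {
  args <- list(...)
  defaults <- list(n_proteins = 400,
                   n_patients = c(HC = 3, DC = 3, AF = 3, RV = 3),
                   n_replicates = 2, counts_depth = 5000, sub_size = 25)
  cfg <- do.call(synthetic_config, utils::modifyList(defaults, args))
  generate_cohort(cfg, seed = seed)
}

# brute-force oracles -------------------------------------------------------

# step-up FDR adjustment, straight from the definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# step-down familywise adjustment, straight from the definition
holm_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((n - seq_len(n) + 1) * p[o]))
  out <- numeric(n)
  out[o] <- adj
  out
}

# one-tailed hypergeometric tail sum for a 2x2 table (rows: subset/rest,
# cols: in-category/not), alternative "greater"
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); k1 <- sum(tab[, 1]); n <- sum(tab)
  a_max <- min(r1, k1)
  sum(vapply(tab[1, 1]:a_max, function(a)
    stats::dhyper(a, k1, n - k1, r1), numeric(1)))
}

# exact one-tailed Mann-Whitney p by exhaustive enumeration of group
# assignments (tie-free data)
mw_oracle <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[seq_along(x)])
  combs <- utils::combn(length(pooled), length(x))
  stat <- apply(combs, 2, function(idx) sum(r[idx]))
  mean(stat >= obs)
}
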