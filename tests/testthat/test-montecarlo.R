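make_context_tables <- function(n = 600, seed = 1, shift = c(0, 0, 0, 0),
                                subset_idx = 1:40, noise = 0.05) {
  set.seed(seed)
  base <- rnorm(n)
  ids <- sprintf("SP%04d", 1:n)
  tabs <- lapply(seq_along(CONTEXTS), function(ci) {
    s <- base + rnorm(n, 0, noise)
    s[subset_idx] <- s[subset_idx] + shift[ci]
    make_sigma_table(s, ids = ids, context = CONTEXTS[ci])
  })
  names(tabs) <- CONTEXTS
  tabs
}

test_that("identical context tables defeat the strict criterion", {
  st <- make_sigma_table(rnorm(300, 0, 1) + 0)
  tabs <- list(HC = st, DC = st, AF = st, RV = st)
  res <- escalation_test(tabs, protein_set("s", st$id[1:20]), K = 1000,
                         criterion = "strict", seed = 1)
  expect_false(res$pattern_observed)   # exact ties cannot rise strictly
  expect_equal(res$p, 1)
  # and no random draw can strictly escalate over identical tables
  expect_true(res$at_floor)
})

test_that("planted escalation is detected and relaxed p bounds strict p", {
  tabs <- make_context_tables(shift = c(0, 0.2, 0.4, 0.6), seed = 2)
  sub <- protein_set("planted", tabs$HC$id[1:40])
  strict <- escalation_test(tabs, sub, K = 2e4, criterion = "strict",
                            seed = 7)
  relaxed <- escalation_test(tabs, sub, K = 2e4, criterion = "relaxed",
                             seed = 7)
  expect_true(strict$pattern_observed)
  expect_lt(strict$p, 0.05)
  # same draws: strict exceedance cannot surpass relaxed exceedance
  expect_lte(strict$exceed, relaxed$exceed)
  expect_lte(strict$p_null, relaxed$p_null)
})

test_that("escalation results are bit-reproducible under a fixed seed", {
  tabs <- make_context_tables(seed = 3)
  sub <- protein_set("s", tabs$HC$id[1:30])
  a <- escalation_test(tabs, sub, K = 5000, seed = 99)
  b <- escalation_test(tabs, sub, K = 5000, seed = 99)
  expect_identical(a$exceed, b$exceed)
  expect_identical(a$p, b$p)
  c_ <- escalation_test(tabs, sub, K = 5000, seed = 100)
  expect_false(identical(a$exceed, c_$exceed))
})

test_that("chance-probability estimates at K and 10K are consistent", {
  tabs <- make_context_tables(seed = 4, noise = 0.5)
  sub <- protein_set("s", tabs$HC$id[1:30])
  K1 <- 4000; K2 <- 40000
  r1 <- escalation_test(tabs, sub, K = K1, criterion = "relaxed", seed = 5)
  r2 <- escalation_test(tabs, sub, K = K2, criterion = "relaxed", seed = 6)
  se <- sqrt(r2$p_null * (1 - r2$p_null) * (1 / K1 + 1 / K2))
  expect_lt(abs(r1$p_null - r2$p_null), 4 * se)
})

test_that("escalation handles proteins missing from some contexts", {
  tabs <- make_context_tables(n = 400, seed = 8)
  # drop a third of the proteins from HC only: universe is the union
  tabs$HC <- tabs$HC[-(1:133), ]
  class(tabs$HC) <- c("supersaturation_table", "data.frame")
  attr(tabs$HC, "context") <- "HC"
  sub <- protein_set("s", sprintf("SP%04d", 200:240))
  res <- escalation_test(tabs, sub, K = 2000, seed = 11)
  expect_identical(res$universe_size, 400L)
  expect_true(is.finite(res$p_null))
})

test_that("comparative delta test is symmetric under a null of equal contexts", {
  set.seed(12)
  ids <- sprintf("SP%04d", 1:500)
  t1 <- make_sigma_table(rnorm(500), ids = ids, context = "DC")
  t2 <- make_sigma_table(rnorm(500), ids = ids, context = "AF")
  res <- comparative_delta_test(t1, t2, protein_set("s", ids[1:40]),
                                K = 20000, seed = 13)
  # both contexts drawn from one distribution: the observed difference is
  # a typical draw from the trial null, so p is central
  expect_gt(res$p, 0.1)
  expect_lt(res$p, 0.9)

  # literally identical tables: every trial ties the observed zero
  # difference exactly, so no exceedance is possible
  res0 <- comparative_delta_test(t1, t1, protein_set("s", ids[1:40]),
                                 K = 2000, seed = 14)
  expect_equal(res0$dd_observed, 0)
  expect_true(res0$at_floor)
})

test_that("comparative delta detects a planted between-context shift", {
  set.seed(14)
  base <- rnorm(800)
  ids <- sprintf("SP%04d", 1:800)
  t1 <- make_sigma_table(base, ids = ids, context = "DC")
  shifted <- base
  shifted[1:40] <- shifted[1:40] + 0.5
  t2 <- make_sigma_table(shifted, ids = ids, context = "AF")
  res <- comparative_delta_test(t1, t2, protein_set("s", ids[1:40]),
                                K = 50000, seed = 15)
  expect_lt(res$p, 0.01)

  # overwhelming shift: no trial exceeds, p reported at the 1/K floor
  extreme <- base
  extreme[1:40] <- extreme[1:40] + 50
  t3 <- make_sigma_table(extreme, ids = ids, context = "RV")
  res2 <- comparative_delta_test(t1, t3, protein_set("s", ids[1:40]),
                                 K = 5000, seed = 16)
  expect_true(res2$at_floor)
  expect_equal(res2$p, 1 / 5000)
})
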