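test_that("count normalization divides by sample total then length", {
  tab <- make_sample_table(matrix(c(10, 20), 2, 1), lengths = c(100, 200))
  norm <- normalize_counts(tab)
  # 10/30/100 and 20/30/200 are equal, so both renormalize to 0.5
  expect_equal(unname(norm[, 1]), c(0.5, 0.5))

  one <- make_sample_table(matrix(7, 1, 1), lengths = 123)
  expect_equal(unname(normalize_counts(one)[, 1]), 1)

  eq <- make_sample_table(matrix(4, 5, 1), lengths = rep(300, 5))
  expect_equal(unname(normalize_counts(eq)[, 1]), rep(0.2, 5))
})

test_that("normalized columns sum to one and are scale invariant", {
  set.seed(42)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    m <- sample(2:6, 1)
    counts <- matrix(rpois(n * m, 20), n, m)
    counts[1, ] <- counts[1, ] + 1     # keep columns positive
    tab <- make_sample_table(counts, lengths = sample(50:2000, n),
                             contexts = rep("DC", m),
                             patients = rep("p1", m),
                             replicates = seq_len(m))
    norm <- normalize_counts(tab)
    expect_true(all(abs(colSums(norm) - 1) < 1e-9))
    # uniform scaling of one sample's counts leaves its column unchanged
    tab2 <- tab
    tab2$counts[, 1] <- tab$counts[, 1] * 7
    expect_equal(normalize_counts(tab2)[, 1], norm[, 1])
  }
})

test_that("replicate averaging is linear-scale mean then log10", {
  norm <- cbind(s1 = c(0.1, 0.9), s2 = c(0.3, 0.7))
  rownames(norm) <- c("P1", "P2")
  samples <- data.frame(sample_id = c("s1", "s2"), patient_id = "p1",
                        context = "AF", replicate = 1:2)
  ab <- average_and_log(norm, samples, "AF")
  expect_equal(ab$value[ab$id == "P1"], log10(0.2))
  expect_identical(unique(ab$n_used), 2L)

  # single replicate: plain log10
  ab1 <- average_and_log(norm[, 1, drop = FALSE], samples[1, ], "AF")
  expect_equal(ab1$value, log10(c(0.1, 0.9)))

  # zero across replicates: protein absent, not -Inf
  norm0 <- cbind(s1 = c(0, 1), s2 = c(0, 1))
  rownames(norm0) <- c("P1", "P2")
  ab0 <- average_and_log(norm0, samples, "AF")
  expect_identical(ab0$id, "P2")

  expect_error(average_and_log(norm, samples, "RV"), "no samples")
})

test_that("microarray processing logs before averaging and drops flagged arrays", {
  values <- rbind(A = c(10, 100, 5, 7), B = c(-1, 0, 3, 2))
  info <- data.frame(tissue = c("t1", "t2", "cl", "tum"),
                     cell_line = c(FALSE, FALSE, TRUE, FALSE),
                     malignant = c(FALSE, FALSE, FALSE, TRUE),
                     skeletal_muscle = c(TRUE, TRUE, FALSE, FALSE))
  et <- process_microarray(values, info, mode = "cross_tissue")
  expect_equal(et$value[et$id == "A"], mean(c(1, 2)))  # log then mean
  expect_false("B" %in% et$id)                         # values <= 0 dropped

  # skeletal-muscle mode restricts to the muscle arrays
  values2 <- rbind(A = c(10, 1000, rep(50, 4)))
  info2 <- data.frame(tissue = letters[1:6],
                      cell_line = FALSE, malignant = FALSE,
                      skeletal_muscle = c(TRUE, TRUE, rep(FALSE, 4)))
  et2 <- process_microarray(values2, info2, mode = "skeletal_muscle")
  expect_equal(et2$value, 2)
  expect_identical(attr(et2, "provenance"), "microarray_skeletal_muscle")
})

test_that("RNA-seq processing averages FPKM linearly and converts q-values", {
  raw <- data.frame(transcript = c("t1", "t2", "t3"),
                    id = c("A", "A", "B"),
                    fpkm = c(2, 4, 0),
                    qvalue = c(0.02, 0.08, 0.5),
                    lfc = c(-1, -0.5, 0.2))
  et <- process_rnaseq(raw, tail = "down")
  expect_equal(et$value[et$id == "A"], log10(3))   # mean then log
  # largest q (0.08) halved because its transcript is down
  expect_equal(et$qvalue[et$id == "A"], 0.04)
  expect_false("B" %in% et$id)                     # FPKM <= 0 excluded

  # direction mismatch: 1 - q/2
  raw_up <- data.frame(transcript = "t", id = "C", fpkm = 5,
                       qvalue = 0.1, lfc = 0.8)
  expect_equal(process_rnaseq(raw_up, tail = "down")$qvalue, 0.95)

  raw_bad <- data.frame(transcript = "t", id = "C", fpkm = 5, qvalue = 1.2)
  expect_error(process_rnaseq(raw_bad), "q-values")
})
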