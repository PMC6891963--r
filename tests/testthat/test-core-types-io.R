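test_that("sample table validation enforces its invariants", {
  counts <- matrix(c(10, 0, 20, 30), 2, 2, byrow = TRUE)
  tab <- make_sample_table(rbind(c(10, 0), c(20, 30)), lengths = c(100, 200))
  expect_identical(unname(tab$counts), rbind(c(10, 0), c(20, 30)))

  expect_error(make_sample_table(rbind(c(10, 0), c(20, 30)),
                                 lengths = c(100, 200),
                                 contexts = c("HC", "XX")),
               "unknown context")
  expect_error(make_sample_table(rbind(c(-1, 1), c(2, 3)),
                                 lengths = c(100, 200)),
               "non-negative")
  expect_error(make_sample_table(rbind(c(0, 1), c(0, 3)),
                                 lengths = c(100, 200)),
               "positive count")
  # dimension disagreement between matrix and metadata
  expect_error(sample_table(matrix(1, 2, 2),
                            proteins = data.frame(id = "a", length = 10),
                            samples = data.frame(sample_id = c("s1", "s2"),
                                                 patient_id = "p",
                                                 context = "HC",
                                                 replicate = 1:2)),
               "protein records")
})

test_that("sample tables round-trip through TSV bit-exactly", {
  co <- small_cohort(seed = 5, n_proteins = 500)
  tab <- co$tables$HC
  d <- withr::local_tempdir()
  write_sample_table(tab, file.path(d, "c.tsv"), file.path(d, "m.tsv"))
  back <- read_sample_table(file.path(d, "c.tsv"), file.path(d, "m.tsv"))
  expect_identical(back$counts, tab$counts)
  expect_identical(back$proteins, tab$proteins)
  expect_identical(back$samples, tab$samples)
})

test_that("count table reader rejects malformed inputs", {
  d <- withr::local_tempdir()
  cf <- file.path(d, "c.tsv"); mf <- file.path(d, "m.tsv")
  writeLines(c("id\tlength\ts1\ts2", "P1\t100\t1\t2", "P2\t50\t3\t4"), cf)
  writeLines(c("sample_id\tpatient_id\tcontext\treplicate",
               "s1\tp1\tHC\t1"), mf)
  expect_error(read_sample_table(cf, mf), "not referenced")
  writeLines(c("sample_id\tpatient_id\tcontext\treplicate",
               "s1\tp1\tHC\t1", "s2\tp1\tHC\t2", "s3\tp1\tHC\t3"), mf)
  expect_error(read_sample_table(cf, mf), "absent sample column")
})

test_that("protein sets deduplicate, honor nominal N headers, round-trip", {
  d <- withr::local_tempdir()
  f <- file.path(d, "set.txt")
  writeLines(c("P1", "P2", "P2"), f)
  ps <- read_protein_set(f)
  expect_setequal(ps$members, c("P1", "P2"))
  expect_identical(ps$nominal_size, 2L)

  # nominal size from header may exceed the members listed
  writeLines(c("# name=rv N=53", paste0("P", 1:50)), f)
  ps <- read_protein_set(f)
  expect_identical(ps$nominal_size, 53L)
  expect_identical(ps$name, "rv")
  expect_length(ps$members, 50)

  out <- file.path(d, "rt.txt")
  write_protein_set(ps, out)
  back <- read_protein_set(out)
  expect_identical(back$members, ps$members)
  expect_identical(back$nominal_size, ps$nominal_size)
  expect_identical(back$name, ps$name)

  writeLines(character(0), f)
  expect_error(read_protein_set(f), "empty")
})

test_that("identifier mapping excludes ambiguous and unmapped ids", {
  mapping <- data.frame(raw = c("A", "B", "B", "D"),
                        accession = c("P1", "P1", "P2", "P9"),
                        reviewed = c(TRUE, TRUE, TRUE, FALSE))
  res <- map_identifiers(c("A", "B", "C", "D"), mapping)
  expect_identical(res$accession, c("P1", NA, NA, NA))
  expect_identical(res$status, c("mapped", "ambiguous", "unmapped", "unmapped"))
})

test_that("propensity tables require at least one finite score per protein", {
  expect_error(propensity_table(data.frame(id = "P1")), "at least one")
  expect_error(
    propensity_table(data.frame(id = c("P1", "P2"),
                                z_agg = c(1, NA), z_agg_sc = c(0, NA))),
    "at least one propensity score")
  pt <- propensity_table(data.frame(id = c("P1", "P2"),
                                    z_agg = c(1, NA), z_agg_sc = c(0, 2)))
  expect_s3_class(pt, "propensity_table")
})
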