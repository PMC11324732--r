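test_that("read_design validates, aliases, and rejects duplicates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  d <- data.frame(sample = paste0("S", 1:12),
                  condition = rep(c("T22", "H4", "H24", "R22"), each = 3),
                  replicate = rep(1:3, 4))
  write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
  des <- read_design(f)
  expect_s3_class(des, "sample_design")
  expect_equal(nrow(des), 12)
  expect_equal(des$condition, d$condition)

  # alias resolution, built-in and user-supplied
  d2 <- d
  d2$condition[4:6] <- "37C_4h"
  write.table(d2, f, sep = "\t", quote = FALSE, row.names = FALSE)
  des2 <- read_design(f, aliases = c("37C_4h" = "H4"))
  expect_equal(des2$condition[4:6], rep("H4", 3))
  expect_equal(read_design(f)$condition[4:6], rep("H4", 3)) # built-in too

  d3 <- d
  d3$sample[2] <- "S1"
  write.table(d3, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_design(f), "duplicate sample_id")

  d4 <- d
  d4$condition[1] <- "frozen"
  write.table(d4, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_design(f), "unknown condition")
})

test_that("aggregate_peptides sums observed peptides and propagates all-missing", {
  des <- simulate_design(1)
  des <- des[des$condition %in% c("T22", "H4"), ]
  peps <- data.frame(peptide_id = c("p1", "p2", "p3", "p4"),
                     accession = c("P1", "P1", "P2", "P2"),
                     T22_r1 = c(10, 20, 10, NA),
                     H4_r1 = c(NA, NA, 5, 7),
                     check.names = FALSE)
  m <- aggregate_peptides(peps, des)
  expect_equal(abundance_scale(m), "raw")
  expect_equal(m["P1", "T22_r1"], 30)      # plain sum
  expect_equal(m["P2", "T22_r1"], 10)      # missing excluded
  expect_true(is.na(m["P1", "H4_r1"]))     # all-missing propagates
  expect_equal(m["P2", "H4_r1"], 12)

  peps$accession[1] <- ""
  expect_error(aggregate_peptides(peps, des), "empty protein accession")
})

test_that("peptide aggregation conserves totals on fully observed tables", {
  des <- simulate_design(3)
  set.seed(41)
  peps <- data.frame(peptide_id = paste0("pep", 1:60),
                     accession = sample(paste0("P", 1:12), 60, replace = TRUE),
                     matrix(rexp(60 * 12, 1 / 1000), 60,
                            dimnames = list(NULL, des$sample)),
                     check.names = FALSE)
  m <- aggregate_peptides(peps, des)
  expect_equal(colSums(unclass(m)),
               colSums(as.matrix(peps[, des$sample])))
})

test_that("rpm normalization and its column-sum identity", {
  cts <- matrix(c(500L, 3L, 0L, 10L), 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  tc <- transcript_counts(cts, c(s1 = 1e6, s2 = 1e3))
  rpm <- rpm_normalize(tc)
  expect_equal(abundance_scale(rpm), "rpm")
  expect_equal(rpm["g1", "s1"], 500)
  expect_equal(rpm["g2", "s2"], 10 / 1e3 * 1e6)
  expect_equal(rpm["g2", "s1"], 3)
  expect_equal(unname(rpm["g1", "s2"]), 0)  # zero preserved

  # totals equal to column sums -> rpm columns sum to exactly 1e6
  set.seed(7)
  cts2 <- matrix(rpois(50, 300), 10, 5,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
  rpm2 <- rpm_normalize(transcript_counts(cts2))
  expect_equal(unname(colSums(unclass(rpm2))), rep(1e6, 5))

  expect_error(transcript_counts(cts, c(s1 = 0, s2 = 1e3)),
               "strictly positive")
  expect_error(transcript_counts(matrix(-1L, 1, 1,
                                        dimnames = list("g", "s"))),
               "non-negative")
})

test_that("log2_transform censors zeros and inverts 2^x", {
  m <- abundance_matrix(matrix(c(8, 1, 0, NA), 2,
                               dimnames = list(c("a", "b"), c("s1", "s2"))),
                        scale = "raw")
  lm <- log2_transform(m)
  expect_equal(abundance_scale(lm), "log2")
  expect_equal(lm["a", "s1"], 3)
  expect_equal(lm["b", "s1"], 0)
  expect_true(is.na(lm["a", "s2"]))   # 0 -> missing (censoring)
  expect_true(is.na(lm["b", "s2"]))

  set.seed(5)
  x <- matrix(rnorm(40, 20, 3), 10, 4,
              dimnames = list(paste0("p", 1:10), paste0("s", 1:4)))
  back <- log2_transform(abundance_matrix(2^x, scale = "raw"))
  expect_equal(unclass(back), x, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("presence_filter retains by per-condition observation counts", {
  des <- simulate_design(3)
  v <- matrix(rnorm(3 * 12, 20), 3, 12,
              dimnames = list(c("keep", "drop", "edge"), des$sample))
  v["drop", ] <- NA
  v["drop", "T22_r1"] <- 20                      # 1 obs in one condition
  v["edge", ] <- NA
  v["edge", c("H4_r1", "H4_r2")] <- 20           # 2 obs in H4
  m <- abundance_matrix(v, scale = "log2")
  f <- presence_filter(m, des, min_per_condition = 2)
  expect_setequal(rownames(f), c("keep", "edge"))
  expect_equal(attr(f, "filter_mode"), "global")

  f0 <- presence_filter(m, des, min_per_condition = 0)
  expect_equal(dim(f0), dim(m))                  # identity at min = 0
  expect_error(presence_filter(m, des, min_per_condition = 4),
               "replicate count")
})

test_that("left-censored imputation is seeded, low, and off-scale-safe", {
  des <- simulate_design(3)
  set.seed(11)
  v <- matrix(rnorm(200 * 12, 20, 2), 200, 12,
              dimnames = list(sprintf("p%03d", 1:200), des$sample))
  v[sample(length(v), 150)] <- NA
  m <- abundance_matrix(v, scale = "log2")

  i1 <- impute_left_censored(m, seed = 42)
  i2 <- impute_left_censored(m, seed = 42)
  expect_identical(unclass(i1), unclass(i2))     # determinism
  expect_false(anyNA(i1))
  # untouched where observed
  expect_equal(unclass(i1)[!is.na(v)], v[!is.na(v)])

  # imputed values sit below the per-sample observed median (quantile 0.01)
  for (j in seq_len(ncol(v))) {
    miss <- is.na(v[, j])
    if (!any(miss)) next
    expect_true(all(unclass(i1)[miss, j] <=
                      quantile(v[, j], 0.5, na.rm = TRUE)))
  }

  full <- abundance_matrix(v[rowSums(is.na(v)) == 0, , drop = FALSE],
                           scale = "log2")
  expect_identical(unclass(impute_left_censored(full, seed = 1)),
                   unclass(full))                # identity with no missing

  raw <- abundance_matrix(2^v[1:20, ], scale = "raw")
  expect_error(impute_left_censored(raw, seed = 1), "log2")
})

test_that("abundance tables round-trip through TSV to 12 significant digits", {
  set.seed(13)
  v <- matrix(rexp(60, 1e-6), 12, 5,
              dimnames = list(sprintf("p%02d", 1:12), paste0("s", 1:5)))
  v[c(3, 17, 40)] <- NA
  m <- abundance_matrix(v, scale = "raw")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_abundance(m, f)
  m2 <- read_abundance(f, scale = "raw")
  expect_identical(is.na(unclass(m2)), is.na(v))
  expect_equal(unclass(m2), v, tolerance = 1e-12, ignore_attr = TRUE)
  # empty fields, never 0, for missing values
  raw_lines <- readLines(f)
  expect_true(any(grepl("\t\t|\t$", raw_lines)))
})
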