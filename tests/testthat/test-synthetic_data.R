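test_that("class mean profiles are consistent with the decision table", {
  prof <- class_mean_profiles(2)
  expect_equal(prof$EG, c(0, 2, 2, 0))
  expect_equal(prof$"NULL", rep(0, 4))
  cons <- canonical_contrasts()
  for (cls in kinetic_groups()) {
    for (d in c(1, -1)) {
      mu <- prof[[cls]] * d
      names(mu) <- conditions()
      pattern <- sign(mu[cons$numerator] - mu[cons$denominator])
      got <- classify_pattern(as.integer(pattern))
      expect_equal(got$group, cls)
      expect_equal(got$direction, as.integer(d))
    }
  }
  # CG and NULL match no kinetic rule
  for (cls in c("CG", "NULL")) {
    mu <- prof[[cls]]
    names(mu) <- conditions()
    pattern <- sign(mu[cons$numerator] - mu[cons$denominator])
    expect_equal(classify_pattern(as.integer(pattern))$group, "UNASSIGNED")
  }
})

test_that("simulate_proteome is seeded, noise-faithful, and shaped right", {
  cfg <- sim_config(n_per_class = c(EG = 20, RG = 20, "NULL" = 60),
                    seed = 33)
  s1 <- simulate_proteome(cfg)
  s2 <- simulate_proteome(cfg)
  expect_identical(unclass(s1$abundance), unclass(s2$abundance))
  expect_identical(s1$truth, s2$truth)
  expect_equal(dim(s1$abundance), c(100, 12))
  expect_equal(abundance_scale(s1$abundance), "raw")

  # near-noise-free limit: replicate means equal true means
  cfg0 <- sim_config(n_per_class = c(EG = 10, "NULL" = 10), sigma = 1e-9,
                     lod_quantile = 0, mcar_rate = 0, seed = 2)
  s0 <- simulate_proteome(cfg0)
  lv <- log2(unclass(s0$abundance))
  for (cc in conditions()) {
    sm <- s0$design$sample[s0$design$condition == cc]
    expect_equal(unname(rowMeans(lv[, sm])),
                 s0$truth[[paste0("mu_", cc)]], tolerance = 1e-6)
  }
})

test_that("realized missingness tracks the censoring oracle", {
  # LOD at the realized per-sample quantile q censors a fraction q exactly;
  # MCAR then removes a further mcar_rate of the remainder
  q <- 0.05; mcar <- 0.02
  fr <- vapply(1:10, function(seed) {
    cfg <- sim_config(n_per_class = c("NULL" = 1000), lod_quantile = q,
                      mcar_rate = mcar, seed = seed)
    mean(is.na(simulate_proteome(cfg)$abundance))
  }, 0)
  expected <- q + mcar * (1 - q)
  expect_lt(abs(mean(fr) - expected), 0.02)
})

test_that("simulate_transcripts honours the coupling parameter", {
  # rho = 1, tiny dispersion, deep library: profile correlation -> 1.
  # A large flat background keeps per-condition read composition stable,
  # so rpm normalization does not distort the planted profiles
  cfg <- sim_config(n_per_class = c(EG = 30, LG = 30, RG = 30,
                                    "NULL" = 2000),
                    rho = 1, nb_dispersion = 1e-8, library_size = 5e8,
                    seed = 3)
  sim <- simulate_proteome(cfg)
  planted <- sim$truth$class != "NULL"
  tx <- simulate_transcripts(sim$truth, cfg)
  expect_identical(tx$counts$counts,
                   simulate_transcripts(sim$truth, cfg)$counts$counts)
  rpm <- rpm_normalize(tx$counts)
  lr <- log2(unclass(rpm) + 1)
  mu_prot <- as.matrix(sim$truth[, paste0("mu_", conditions())])
  rs <- vapply(which(planted), function(i) {
    rprof <- vapply(conditions(), function(cc) {
      mean(lr[i, tx$design$sample[tx$design$condition == cc]])
    }, 0)
    cor(mu_prot[i, ], rprof)
  }, 0)
  expect_gte(stats::median(rs), 0.99)

  # rho = 0: wide null distribution of 4-point correlations, |r| small on
  # average but far from zero pointwise
  cfg0 <- sim_config(n_per_class = c("NULL" = 2000), rho = 0, seed = 4)
  sim0 <- simulate_proteome(cfg0)
  tx0 <- simulate_transcripts(sim0$truth, cfg0)
  lr0 <- log2(unclass(rpm_normalize(tx0$counts)) + 1)
  m0 <- log2_transform(sim0$abundance)
  corr <- correlate_omics(m0, rpm_normalize(tx0$counts), sim0$design,
                          tx0$design)
  expect_lte(mean(abs(corr$records$r), na.rm = TRUE), 0.55)
})

test_that("simulated peptides sum back to protein intensities", {
  cfg <- sim_config(n_per_class = c(EG = 15, "NULL" = 15), seed = 8)
  sim <- simulate_proteome(cfg)
  peps <- simulate_peptides(sim, seed = 8)
  agg <- aggregate_peptides(peps, sim$design)
  common <- rownames(sim$abundance)
  expect_equal(unclass(agg)[common, ], unclass(sim$abundance)[common, ],
               tolerance = 1e-9)
})

test_that("evaluate_recovery scores perfect and degenerate assignments", {
  truth <- data.frame(accession = paste0("P", 1:30),
                      class = rep(c("EG", "RG", "NULL"), each = 10),
                      direction = rep(c(1L, 1L, 0L), each = 10))
  perfect <- structure(
    data.frame(accession = paste0("P", 1:20),
               group = rep(c("EG", "RG"), each = 10),
               direction = 1L),
    class = c("kinetic_assignment", "data.frame"))
  ev <- evaluate_recovery(perfect, truth)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$fdp_dap, 0)
  expect_equal(ev$per_class$recall[ev$per_class$class == "EG"], 1)

  nothing <- perfect
  nothing$group <- "UNASSIGNED"
  ev0 <- evaluate_recovery(nothing, truth)
  expect_equal(ev0$accuracy, 0)
  planted_classes <- intersect(kinetic_groups(), truth$class)
  expect_true(all(ev0$per_class$recall[ev0$per_class$class %in%
                                         planted_classes] == 0))
})

test_that("recovery improves with effect size and degrades with noise", {
  # 2x2 corner check of the monotonicity surface, averaged over 3 seeds
  acc <- function(delta, sigma) {
    mean(vapply(1:3, function(seed) {
      cfg <- sim_config(n_per_class = c(EG = 15, LG = 15, TG = 15,
                                        EPG = 15, LPG = 15, RG = 15,
                                        "NULL" = 150),
                        delta = delta, sigma = sigma, seed = seed,
                        lod_quantile = 0, mcar_rate = 0)
      sim <- simulate_proteome(cfg)
      ct <- run_contrasts(log2_transform(sim$abundance), sim$design)
      evaluate_recovery(classify_all(ct), sim$truth)$accuracy
    }, 0))
  }
  a_easy <- acc(2, 0.2)
  a_small_effect <- acc(0.4, 0.2)
  a_noisy <- acc(2, 1.2)
  expect_gte(a_easy, a_small_effect)
  expect_gte(a_easy, a_noisy)
})
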