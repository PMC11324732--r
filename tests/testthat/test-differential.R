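test_that("pooled_stats matches hand computations and flags untestable", {
  r <- pooled_stats(c(5, 5, 5), c(3, 3, 3))
  expect_equal(r$log2fc, 2)
  expect_equal(r$s_g_sq, 0)
  expect_equal(r$df_g, 4)

  expect_equal(pooled_stats(c(1, 2, 3), c(1, 2, 3))$log2fc, 0)

  r2 <- pooled_stats(c(1, 2), c(3, 5))
  expect_equal(r2$log2fc, -2.5)
  expect_equal(r2$s_g_sq, (0.5 + 2) / 2)   # hand pooled variance
  expect_equal(r2$df_g, 2)

  r3 <- pooled_stats(c(1, NA, NA), c(3, 4, 5))
  expect_true(r3$untestable)
  expect_true(is.na(r3$log2fc))
})

test_that("variance prior recovers a planted scaled-chisq generator", {
  # s_g^2 ~ s0^2 chisq_4 / 4 with s0^2 = 0.09, d0 = Inf in the generator
  # sense is not what we plant; draw from the full hierarchical model:
  # 1/sigma^2 ~ (1/(d0 s0^2)) chisq_d0, s_g^2 | sigma^2 ~ sigma^2 chisq_4/4
  set.seed(101)
  d0_true <- 6; s0_true <- 0.09; n <- 5000
  sigma2 <- d0_true * s0_true / rchisq(n, d0_true)
  s2 <- sigma2 * rchisq(n, 4) / 4
  prior <- fit_variance_prior(s2, rep(4, n))
  expect_lt(abs(prior$s0_sq - s0_true) / s0_true, 0.10)
  expect_lt(abs(prior$d0 - d0_true) / d0_true, 0.25)

  # cross-check against the established empirical-Bayes fit
  fd <- limma::fitFDist(s2, df1 = 4)
  expect_equal(prior$s0_sq, fd$scale, tolerance = 1e-6)
  expect_equal(prior$d0, fd$df2, tolerance = 1e-6)

  # exactly constant variances -> infinite prior df
  pc <- fit_variance_prior(rep(0.25, 100), rep(4, 100))
  expect_true(is.infinite(pc$d0))
  expect_equal(pc$s0_sq, 0.25, tolerance = 1e-9)

  # permutation invariance
  perm <- sample(n)
  p2 <- fit_variance_prior(s2[perm], rep(4, n))
  expect_equal(p2$d0, prior$d0)
  expect_equal(p2$s0_sq, prior$s0_sq)

  expect_error(fit_variance_prior(rep(0, 60), rep(4, 60)), "zero")
})

test_that("moderated_t: null case, ordinary-t limit, and shrinkage limits", {
  pr <- variance_prior(4, 0.05)
  r <- moderated_t(0, 0.04, 4, pr, 3, 3)
  expect_equal(r$t_mod, 0)
  expect_equal(r$p_raw, 1)

  # d0 = 0 reduces to the ordinary pooled two-sample t-test
  set.seed(3)
  x <- matrix(rnorm(30, 20, 0.5), 10)
  y <- matrix(rnorm(30, 20, 0.5), 10)
  for (i in 1:10) {
    ps <- pooled_stats(x[i, ], y[i, ])
    mt <- moderated_t(ps$log2fc, ps$s_g_sq, ps$df_g,
                      variance_prior(0, 1), ps$n_x, ps$n_y)
    tt <- t.test(x[i, ], y[i, ], var.equal = TRUE)
    expect_equal(mt$p_raw, tt$p.value, tolerance = 1e-10)
    expect_equal(abs(mt$t_mod), abs(unname(tt$statistic)),
                 tolerance = 1e-10)
  }

  # d0 -> large pulls the posterior variance to s0_sq
  big <- moderated_t(1, 0.5, 4, variance_prior(1e9, 0.05), 3, 3)
  expect_equal(big$s_post_sq, 0.05, tolerance = 1e-6)

  # s_post_sq = 0 convention
  z <- moderated_t(c(1, 0), c(0, 0), c(4, 4), variance_prior(0, 1), 3, 3)
  expect_equal(z$p_raw, c(0, 1))
})

test_that("posterior variance is a convex combination of prior and sample", {
  set.seed(19)
  n <- 1e4
  s2 <- rexp(n, 5); d0 <- runif(n, 0.5, 20); s0 <- rexp(n, 10) + 1e-4
  for (i in sample(n, 500)) {
    sp <- moderated_t(1, s2[i], 4, variance_prior(d0[i], s0[i]), 3, 3)$s_post_sq
    expect_gte(sp, min(s2[i], s0[i]) - 1e-12)
    expect_lte(sp, max(s2[i], s0[i]) + 1e-12)
  }
})

test_that("adjust_pvalues: plain BH example, monotonicity, pi0 scaling", {
  a <- adjust_pvalues(c(0.01, 0.02, 0.04), method = "bh_plain")
  expect_equal(a$p_adj, c(0.03, 0.03, 0.04))
  expect_equal(a$calibration$pi0_hat, 1)

  a1 <- adjust_pvalues(rep(1, 10))
  expect_equal(a1$p_adj, rep(1, 10))
  expect_equal(a1$calibration$pi0_hat, 1)

  expect_equal(adjust_pvalues(numeric(0))$p_adj, numeric(0))

  set.seed(8)
  for (rep in 1:20) {
    p <- runif(50)^2
    a <- adjust_pvalues(p)
    o <- order(p)
    expect_true(all(diff(a$p_adj[o]) >= -1e-15))       # order-preserving
    expect_true(all(a$p_adj >= a$calibration$pi0_hat * p - 1e-15))
    expect_true(all(a$p_adj >= p - 1e-15))             # clipped to [p, 1]
    expect_true(all(a$p_adj <= 1))
    # calibrated values never exceed plain BH
    expect_true(all(a$p_adj <= oracle_bh(p) + 1e-12))
  }
})

test_that("call_significance applies inclusive per-contrast thresholds", {
  th <- default_thresholds()
  expect_equal(th$alpha, c(C1 = 5e-4, C2 = 1e-3, C3 = 1e-3, C4 = 4e-4,
                           C5 = 7e-4, C6 = 5e-4))
  call <- call_significance(log2fc = c(1.2, 0.8, -2, 1),
                            p_raw = c(1e-4, 5e-4, 1e-5, 0.01),
                            p_adj = rep(NA_real_, 4),
                            untestable = rep(FALSE, 4), th, "C1")
  expect_equal(call, c(1L, 1L, -1L, 0L))   # boundary p = alpha is significant
})

test_that("run_contrasts: antisymmetry, DAP identity, planted power", {
  cfg <- sim_config(n_per_class = c(EG = 100, "NULL" = 400), seed = 21,
                    lod_quantile = 0, mcar_rate = 0)
  sim <- simulate_proteome(cfg)
  m <- log2_transform(sim$abundance)
  ct <- run_contrasts(m, sim$design)

  # DAP set = union over contrasts of nonzero calls
  expect_setequal(dap_set(ct), unique(ct$accession[ct$call != 0]))

  # planted +2 in H4 and H24 (EG class, direction +1): power in C1 and C2
  up <- sim$truth$accession[sim$truth$class == "EG" &
                              sim$truth$direction == 1]
  for (cc in c("C1", "C2")) {
    calls <- ct$call[ct$accession %in% up & ct$contrast == cc]
    expect_gte(mean(calls == 1), 0.95)
  }

  # antisymmetry: swapping numerator/denominator negates fc and t
  des <- sim$design
  swapped <- des
  swapped$condition[des$condition == "H4"] <- "T22"
  swapped$condition[des$condition == "T22"] <- "H4"
  ct2 <- run_contrasts(m, swapped)
  a <- ct[ct$contrast == "C1", ]; b <- ct2[ct2$contrast == "C1", ]
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$t_mod, -b$t_mod)
  expect_equal(a$p_raw, b$p_raw, tolerance = 1e-12)

  expect_error(run_contrasts(m, des[des$condition != "R22", ]), "R22")
})

test_that("untestable proteins are retained and flagged, never dropped", {
  des <- simulate_design(3)
  set.seed(77)
  v <- matrix(rnorm(60 * 12, 20, 0.3), 60, 12,
              dimnames = list(sprintf("p%02d", 1:60), des$sample))
  v[1, des$sample[des$condition == "T22"][1:2]] <- NA  # 1 obs in T22
  m <- abundance_matrix(v, scale = "log2")
  ct <- run_contrasts(m, des)
  r <- ct[ct$accession == "p01" & ct$contrast == "C1", ]
  expect_true(r$untestable)
  expect_equal(r$call, 0L)
  expect_true(all(table(ct$accession) == 6))
})
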