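#' Canonical condition contrasts
#'
#' The six pairwise comparisons spanning the time course, in the fixed
#' order used throughout: C1 = H4 vs T22, C2 = H24 vs T22, C3 = R22 vs T22,
#' C4 = H24 vs H4, C5 = R22 vs H4, C6 = R22 vs H24. The first condition is
#' the numerator of the fold change.
#'
#' @return Data frame with columns `id`, `numerator`, `denominator`.
#' @export
canonical_contrasts <- function() {
  data.frame(
    id = paste0("C", 1:6),
    numerator   = c("H4", "H24", "R22", "H24", "R22", "R22"),
    denominator = c("T22", "T22", "T22", "H4", "H4", "H24"),
    stringsAsFactors = FALSE
  )
}

#' Default per-contrast significance thresholds
#'
#' Raw p-value cutoffs tuned so that the realized FDR across contrasts sits
#' near 1%: alpha(C1..C6) = 0.0005, 0.001, 0.001, 0.0004, 0.0007, 0.0005.
#'
#' @param mode `"raw_p"` (default) thresholds raw p-values; `"adjusted_p"`
#'   thresholds calibrated BH-adjusted p-values.
#' @param alpha optional named numeric vector `C1..C6` overriding the
#'   defaults.
#' @return A `contrast_thresholds` list with `alpha` and `mode`.
#' @export
default_thresholds <- function(mode = c("raw_p", "adjusted_p"), alpha = NULL) {
  mode <- match.arg(mode)
  a <- c(C1 = 5e-4, C2 = 1e-3, C3 = 1e-3, C4 = 4e-4, C5 = 7e-4, C6 = 5e-4)
  if (!is.null(alpha)) {
    if (!all(names(alpha) %in% names(a))) stop("alpha names must be C1..C6")
    a[names(alpha)] <- alpha
  }
  if (any(a <= 0) || any(a >= 1)) stop("alpha must lie in (0,1)")
  structure(list(alpha = a, mode = mode), class = "contrast_thresholds")
}

#' Two-sample pooled statistics
#'
#' @param x,y numeric vectors of replicate log2 intensities (`NA` allowed).
#' @return List with `log2fc` = mean(x) - mean(y), pooled variance
#'   `s_g_sq`, residual degrees of freedom `df_g`, and the observed counts
#'   `n_x`, `n_y`. With fewer than 2 observed values on either side the
#'   protein is untestable: all statistics are `NA` and `untestable` is
#'   `TRUE`.
#' @export
pooled_stats <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) {
    return(list(log2fc = NA_real_, s_g_sq = NA_real_, df_g = NA_real_,
                n_x = nx, n_y = ny, untestable = TRUE))
  }
  df <- nx + ny - 2
  s2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  list(log2fc = mean(x) - mean(y), s_g_sq = s2, df_g = df,
       n_x = nx, n_y = ny, untestable = FALSE)
}

# vectorized pooled stats over the rows of two matrices
.pooled_stats_matrix <- function(X, Y, min_obs = 2) {
  min_obs <- max(2L, min_obs)
  nx <- rowSums(!is.na(X)); ny <- rowSums(!is.na(Y))
  mx <- rowMeans(X, na.rm = TRUE); my <- rowMeans(Y, na.rm = TRUE)
  vx <- .row_var(X, mx, nx); vy <- .row_var(Y, my, ny)
  df <- nx + ny - 2
  s2 <- ifelse(df > 0, ((nx - 1) * vx + (ny - 1) * vy) / df, NA_real_)
  untestable <- nx < min_obs | ny < min_obs
  data.frame(log2fc = ifelse(untestable, NA_real_, mx - my),
             s_g_sq = ifelse(untestable, NA_real_, s2),
             df_g = ifelse(untestable, NA_real_, df),
             n_x = nx, n_y = ny, untestable = untestable)
}

.row_var <- function(X, mu, n) {
  ss <- rowSums((X - mu)^2, na.rm = TRUE)
  ifelse(n > 1, ss / (n - 1), 0)
}

# Newton inversion of the trigamma function (psigamma deriv 1),
# solving trigamma(y) = x for y > 0.
trigamma_inverse <- function(x) {
  out <- x
  ok <- is.finite(x) & x > 0
  # large x -> small y: trigamma(y) ~ 1/y^2 + 1/y ; small x -> y ~ 1/x
  y <- 0.5 + 1 / x[ok]
  for (i in 1:60) {
    tri <- psigamma(y, 1)
    dif <- tri * (1 - tri / x[ok]) / psigamma(y, 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  out[ok] <- y
  out[is.finite(x) & x <= 0] <- Inf
  out
}

#' Construct a variance prior
#' @param d0 prior degrees of freedom (> 0, may be `Inf`; 0 is allowed and
#'   turns the moderated test into the ordinary pooled t-test).
#' @param s0_sq prior variance in squared log2-intensity units (> 0).
#' @return A `variance_prior` list.
#' @export
variance_prior <- function(d0, s0_sq) {
  stopifnot(d0 >= 0, s0_sq > 0 || d0 == 0)
  structure(list(d0 = d0, s0_sq = s0_sq), class = "variance_prior")
}

#' Fit the empirical-Bayes variance prior
#'
#' Moment-matching of log sample variances to a scaled F distribution, the
#' standard closed form using digamma/trigamma inversion: the prior
#' (`d0`, `s0_sq`) under which s_g^2 ~ s0^2 * F(df_g, d0). Homogeneous
#' variances yield `d0 = Inf`.
#'
#' @param s_g_sq numeric vector of pooled sample variances (one per
#'   testable protein).
#' @param df_g matching residual degrees of freedom.
#' @return A `variance_prior` list with `d0` and `s0_sq`.
#' @export
fit_variance_prior <- function(s_g_sq, df_g) {
  keep <- is.finite(s_g_sq) & is.finite(df_g) & df_g > 0
  s2 <- s_g_sq[keep]; df <- df_g[keep]
  if (!length(s2) || all(s2 == 0)) {
    stop("all sample variances are zero or missing; cannot fit prior",
         call. = FALSE)
  }
  if (length(unique(s2)) == 1) {
    # exactly homogeneous variances: infinite prior df, prior = the constant
    return(structure(list(d0 = Inf, s0_sq = s2[1]),
                     class = "variance_prior"))
  }
  # guard exact zeros (possible in degenerate simulations) like limma does,
  # by flooring at a tiny quantile of the positive variances
  floor_val <- stats::quantile(s2[s2 > 0], 0.01, names = FALSE) * 1e-4
  s2 <- pmax(s2, floor_val)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0 <- exp(emean)
  }
  structure(list(d0 = d0, s0_sq = s0), class = "variance_prior")
}

#' Moderated t-statistic
#'
#' Shrinks the per-protein variance toward the prior and tests the log2
#' fold change: `s_post_sq = (d0 s0_sq + df_g s_g_sq) / (d0 + df_g)`,
#' `t_mod = log2fc / sqrt(s_post_sq (1/n_x + 1/n_y))`, with a two-sided
#' p-value on `df_g + d0` degrees of freedom. With `d0 = 0` this is the
#' ordinary pooled two-sample t-test. When `s_post_sq` is zero the p-value
#' is 0 for a nonzero fold change and 1 otherwise.
#'
#' @param log2fc,s_g_sq,df_g vectors from [pooled_stats()].
#' @param prior a `variance_prior`.
#' @param n_x,n_y observed replicate counts per side.
#' @return Data frame with `log2fc`, `s_g_sq`, `df_g`, `s_post_sq`,
#'   `t_mod`, `p_raw`.
#' @export
moderated_t <- function(log2fc, s_g_sq, df_g, prior, n_x, n_y) {
  d0 <- prior$d0; s0 <- prior$s0_sq
  if (is.infinite(d0)) {
    s_post <- rep(s0, length(log2fc))
  } else {
    s_post <- (d0 * s0 + df_g * s_g_sq) / (d0 + df_g)
  }
  se <- sqrt(s_post * (1 / n_x + 1 / n_y))
  t_mod <- log2fc / se
  df_tot <- df_g + d0
  p <- 2 * stats::pt(-abs(t_mod), df = df_tot)
  zero_se <- is.finite(log2fc) & se == 0
  t_mod[zero_se] <- sign(log2fc[zero_se]) * Inf
  t_mod[zero_se & log2fc == 0] <- 0
  p[zero_se] <- ifelse(log2fc[zero_se] != 0, 0, 1)
  data.frame(log2fc = log2fc, s_g_sq = s_g_sq, df_g = df_g,
             s_post_sq = s_post, t_mod = t_mod, p_raw = p)
}

#' Calibrated Benjamini-Hochberg adjustment
#'
#' Step-up BH adjusted p-values scaled by an estimate of the true-null
#' proportion pi0 (Storey's estimator at a single lambda, default 0.5);
#' `method = "bh_plain"` forces pi0 = 1. Adjusted values are clipped to
#' `[p_raw, 1]` and are monotone in `p_raw`.
#'
#' @param p_raw numeric vector of p-values in \[0,1\].
#' @param method `"storey_lambda"` or `"bh_plain"`.
#' @param lambda tuning point of the Storey estimator.
#' @return List with `p_adj` and `calibration` (`pi0_hat`, `method`,
#'   `fdr_estimate` — the mean adjusted p-value over rejections at the
#'   smallest adjusted value, `NA` when nothing informative).
#' @export
adjust_pvalues <- function(p_raw, method = c("storey_lambda", "bh_plain"),
                           lambda = 0.5) {
  method <- match.arg(method)
  if (!length(p_raw)) {
    return(list(p_adj = numeric(0),
                calibration = list(pi0_hat = 1, method = method,
                                   fdr_estimate = NA_real_)))
  }
  stopifnot(all(p_raw >= 0 & p_raw <= 1, na.rm = TRUE))
  ok <- !is.na(p_raw)
  p <- p_raw[ok]
  n <- length(p)
  pi0 <- if (method == "storey_lambda") {
    min(1, mean(p > lambda) / (1 - lambda))
  } else 1
  if (pi0 <= 0) pi0 <- 1 / n     # degenerate: every p below lambda
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  bh <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  adj <- pmin(1, pmax(p, pi0 * bh))
  out <- rep(NA_real_, length(p_raw))
  out[ok] <- adj
  list(p_adj = out,
       calibration = list(pi0_hat = pi0, method = method,
                          fdr_estimate = min(adj)))
}

#' Signed significance calls
#'
#' @param log2fc,p_raw,p_adj per-protein statistics for one contrast.
#' @param untestable logical flag vector.
#' @param thresholds a `contrast_thresholds`.
#' @param contrast_id one of `"C1"`..`"C6"`.
#' @return Integer vector in \{-1, 0, +1\}: the sign of the fold change when
#'   the thresholded p-value (raw or adjusted per the threshold mode) is at
#'   or below alpha for the contrast, else 0; untestable proteins get 0.
#' @export
call_significance <- function(log2fc, p_raw, p_adj, untestable,
                              thresholds, contrast_id) {
  alpha <- thresholds$alpha[[contrast_id]]
  p <- if (thresholds$mode == "raw_p") p_raw else p_adj
  call <- integer(length(log2fc))
  sig <- !untestable & !is.na(p) & p <= alpha & !is.na(log2fc) & log2fc != 0
  call[sig] <- sign(log2fc[sig])
  call
}

#' Run all six contrasts
#'
#' For each canonical contrast: computes pooled statistics per protein on
#' the observed replicates, fits the variance prior for that contrast,
#' computes moderated t-statistics, calibrated adjusted p-values, and
#' signed significance calls. Untestable proteins (fewer than
#' `min_per_condition` observed replicates on either side) are retained
#' with `untestable = TRUE` and call 0.
#'
#' @param m an `abundance_matrix` on log2 scale.
#' @param design a `sample_design` covering all four conditions.
#' @param thresholds a `contrast_thresholds` (default [default_thresholds()]).
#' @param min_per_condition per-contrast presence requirement (default 2).
#' @return A `contrast_table`: data frame with one row per protein x
#'   contrast (`accession`, `contrast`, `log2fc`, `t_mod`, `p_raw`,
#'   `p_adj`, `call`, `untestable`), with attributes `summary` (per-contrast
#'   up/down counts, pi0 and realized-FDR estimates), `dap` (accessions
#'   significant in >= 1 contrast), `priors`, and `thresholds`.
#' @export
run_contrasts <- function(m, design, thresholds = default_thresholds(),
                          min_per_condition = 2) {
  if (abundance_scale(m) != "log2") {
    stop("run_contrasts requires a log2-scale matrix", call. = FALSE)
  }
  cons <- canonical_contrasts()
  missing_cond <- setdiff(unique(c(cons$numerator, cons$denominator)),
                          unique(design$condition))
  if (length(missing_cond)) {
    stop("condition(s) absent from design: ",
         paste(missing_cond, collapse = ", "), call. = FALSE)
  }
  res <- vector("list", nrow(cons))
  priors <- vector("list", nrow(cons))
  names(priors) <- cons$id
  summaries <- vector("list", nrow(cons))
  for (i in seq_len(nrow(cons))) {
    id <- cons$id[i]
    sx <- design$sample[design$condition == cons$numerator[i]]
    sy <- design$sample[design$condition == cons$denominator[i]]
    ps <- .pooled_stats_matrix(m[, sx, drop = FALSE], m[, sy, drop = FALSE],
                               min_obs = min_per_condition)
    test <- !ps$untestable
    prior <- if (all(ps$s_g_sq[test] == 0)) {
      # exactly noise-free input (sigma = 0 simulations): every call is
      # decided by the s_post = 0 convention, p = 0 iff log2fc != 0
      structure(list(d0 = Inf, s0_sq = 0), class = "variance_prior")
    } else {
      fit_variance_prior(ps$s_g_sq[test], ps$df_g[test])
    }
    priors[[id]] <- prior
    mt <- moderated_t(ps$log2fc, ps$s_g_sq, ps$df_g, prior, ps$n_x, ps$n_y)
    mt$p_raw[ps$untestable] <- NA_real_
    adj <- adjust_pvalues(mt$p_raw)
    call <- call_significance(mt$log2fc, mt$p_raw, adj$p_adj,
                              ps$untestable, thresholds, id)
    res[[i]] <- data.frame(accession = rownames(m), contrast = id,
                           log2fc = mt$log2fc, t_mod = mt$t_mod,
                           p_raw = mt$p_raw, p_adj = adj$p_adj,
                           call = call, untestable = ps$untestable,
                           stringsAsFactors = FALSE)
    alpha <- thresholds$alpha[[id]]
    n_test <- sum(test)
    n_rej <- sum(call != 0)
    # plug-in FDR estimate at the operating threshold
    fdr_hat <- if (n_rej > 0 && thresholds$mode == "raw_p") {
      min(1, adj$calibration$pi0_hat * n_test * alpha / n_rej)
    } else NA_real_
    summaries[[i]] <- data.frame(contrast = id, n_testable = n_test,
                                 up = sum(call > 0), down = sum(call < 0),
                                 pi0_hat = adj$calibration$pi0_hat,
                                 fdr_estimate = fdr_hat,
                                 stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, res)
  rownames(tab) <- NULL
  dap <- sort(unique(tab$accession[tab$call != 0]))
  structure(tab,
            summary = do.call(rbind, summaries),
            dap = dap, priors = priors, thresholds = thresholds,
            class = c("contrast_table", "data.frame"))
}

#' Differentially accumulated proteins of a contrast table
#' @param ct a `contrast_table`.
#' @return Character vector of accessions significant in >= 1 contrast.
#' @export
dap_set <- function(ct) attr(ct, "dap")

#' Per-contrast summary of a contrast table
#' @param ct a `contrast_table`.
#' @return Data frame of up/down counts, pi0 and FDR estimates.
#' @export
contrast_summary <- function(ct) attr(ct, "summary")

#' Write a contrast table to TSV
#' @param ct a `contrast_table`.
#' @param path output path.
#' @export
write_contrasts <- function(ct, path) {
  utils::write.table(as.data.frame(ct), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a contrast table from TSV
#' @param path file written by [write_contrasts()].
#' @return A `contrast_table` (summary attributes recomputed for calls).
#' @export
read_contrasts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$untestable <- as.logical(tab$untestable)
  dap <- sort(unique(tab$accession[tab$call != 0]))
  structure(tab, dap = dap, class = c("contrast_table", "data.frame"))
}
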