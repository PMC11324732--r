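#' PCA scores for sample-level QC
#'
#' Column-centered singular value decomposition of the samples-by-proteins
#' matrix. Missing values are mean-imputed per protein for QC purposes
#' only; this imputation never feeds the statistics.
#'
#' @param m an `abundance_matrix` on log2 scale.
#' @param n_components number of components to return (default 2).
#' @return List: `scores` (samples x components), `variance_fraction`
#'   (per returned component; the fractions over all components sum to 1,
#'   so a subset sums to <= 1).
#' @export
pca_scores <- function(m, n_components = 2) {
  if (ncol(m) < 2) stop("need at least 2 samples", call. = FALSE)
  v <- unclass(m)
  mu <- rowMeans(v, na.rm = TRUE)
  idx <- which(is.na(v), arr.ind = TRUE)
  if (nrow(idx)) v[idx] <- mu[idx[, 1]]
  v <- v[is.finite(mu), , drop = FALSE]
  x <- t(v)                               # samples x proteins
  x <- sweep(x, 2, colMeans(x))
  sv <- svd(x)
  k <- min(n_components, length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)],
                                                      nrow = k)
  rownames(scores) <- colnames(m)
  colnames(scores) <- paste0("PC", seq_len(k))
  varfrac <- sv$d^2 / max(sum(sv$d^2), .Machine$double.xmin)
  list(scores = scores, variance_fraction = varfrac[seq_len(k)])
}

#' Default pipeline configuration
#'
#' @param seed master seed for simulation and clustering reference draws.
#' @return Nested list of every tunable parameter with its default:
#'   presence filtering, optional imputation, the six per-contrast alpha
#'   values and threshold mode, clustering (kmax, B, tau), correlation cut,
#'   and a simulation block (used when no input files are given).
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    quant = list(min_per_condition = 2, filter_mode = "global",
                 impute = FALSE, impute_quantile = 0.01, impute_sd = 0.3,
                 median_center = FALSE),
    diff = list(mode = "raw_p",
                alpha = as.list(default_thresholds()$alpha)),
    cluster = list(kmax = 12, B = 100, tau = 0.8,
                   space = "abundance"),   # or "log2fc"
    correlate = list(cut = 0.5, pseudocount = 1),
    simulate = list(enabled = TRUE)
  )
}

#' Read a pipeline configuration file (YAML or JSON)
#'
#' Missing keys fall back to [default_config()] values.
#'
#' @param path config file path.
#' @return Config list.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("[.]json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  merge_in <- function(base, override) {
    for (k in names(override)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]])) {
        merge_in(base[[k]], override[[k]])
      } else override[[k]]
    }
    base
  }
  merge_in(default_config(), cfg)
}

# optional per-sample median centering on log2 scale
.median_center <- function(m) {
  med <- apply(m, 2, stats::median, na.rm = TRUE)
  abundance_matrix(sweep(unclass(m), 2, med - mean(med)), scale = "log2")
}

#' Run the full pipeline
#'
#' quantify -> differential -> classify -> cluster -> correlate -> report.
#' Inputs are either file paths (protein or peptide abundances plus design,
#' and optionally transcript counts) or, when omitted, a seeded simulation.
#' Stage summaries go to `stderr`; tables and a reproducibility manifest
#' are written under `out_dir`.
#'
#' @param config config list (see [default_config()]) or path to a
#'   YAML/JSON config file.
#' @param proteins,peptides,design,counts,totals optional input file paths;
#'   `proteins` (or `peptides` + aggregation) and `design` switch off the
#'   simulation.
#' @param out_dir output directory (default `"."`); created if needed.
#' @param rules decision rules (default [default_rules()]).
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_all <- function(config = default_config(), proteins = NULL,
                    peptides = NULL, design = NULL, counts = NULL,
                    totals = NULL, out_dir = ".", rules = default_rules()) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, ...) {
    message(sprintf("[heatnuc:%s] %s", stage, sprintf(...)))
  }
  seed <- config$seed
  truth <- NULL; tx <- NULL; rna_design <- NULL
  # --- inputs -------------------------------------------------------------
  if (!is.null(proteins) || !is.null(peptides)) {
    if (is.null(design)) stop("design file required with abundance input",
                              call. = FALSE)
    des <- read_design(design)
    raw <- if (!is.null(proteins)) read_abundance(proteins, scale = "raw")
           else {
      peps <- utils::read.delim(peptides, stringsAsFactors = FALSE,
                                check.names = FALSE,
                                na.strings = c("", "NA"))
      aggregate_peptides(peps, des)
    }
    if (!is.null(counts)) {
      tx <- read_transcript_counts(counts, totals)
      rna_design <- des
    }
    log_stage("input", "%d proteins x %d samples read", nrow(raw), ncol(raw))
  } else {
    simcfg <- do.call(sim_config, c(list(seed = seed),
                                    config$simulate[setdiff(names(config$simulate),
                                                            c("enabled", "seed"))]))
    sim <- simulate_proteome(simcfg)
    txs <- simulate_transcripts(sim$truth, simcfg)
    raw <- sim$abundance; des <- sim$design; truth <- sim$truth
    tx <- txs$counts; rna_design <- txs$design
    log_stage("simulate", "%d proteins simulated (seed %d)", nrow(raw), seed)
  }
  # --- quantify -----------------------------------------------------------
  m <- log2_transform(raw)
  if (isTRUE(config$quant$median_center)) m <- .median_center(m)
  m <- presence_filter(m, des,
                       min_per_condition = config$quant$min_per_condition,
                       mode = config$quant$filter_mode)
  if (isTRUE(config$quant$impute)) {
    m <- impute_left_censored(m, quantile = config$quant$impute_quantile,
                              sd = config$quant$impute_sd, seed = seed)
  }
  qc <- pca_scores(m)
  log_stage("quantify", "%d proteins retained; PC1 %.1f%% of variance",
            nrow(m), 100 * qc$variance_fraction[1])
  # --- differential -------------------------------------------------------
  th <- default_thresholds(mode = config$diff$mode,
                           alpha = unlist(config$diff$alpha))
  ct <- run_contrasts(m, des, thresholds = th,
                      min_per_condition = config$quant$min_per_condition)
  dap <- dap_set(ct)
  cs <- contrast_summary(ct)
  for (i in seq_len(nrow(cs))) {
    log_stage("diff", "%s: %d up, %d down (pi0=%.2f)", cs$contrast[i],
              cs$up[i], cs$down[i], cs$pi0_hat[i])
  }
  log_stage("diff", "%d DAPs (significant in >= 1 contrast)", length(dap))
  write_contrasts(ct, file.path(out_dir, "contrasts.tsv"))
  # --- classify -----------------------------------------------------------
  ka <- classify_all(ct, rules)
  n_classified <- sum(ka$group != "UNASSIGNED")
  log_stage("classify", "%d of %d DAPs in the six kinetic groups",
            n_classified, length(dap))
  write_assignments(ka, file.path(out_dir, "groups.tsv"))
  # --- cluster ------------------------------------------------------------
  unassigned <- ka$accession[ka$group == "UNASSIGNED"]
  clus <- NULL
  if (length(unassigned) >= 3) {
    prof <- if (identical(config$cluster$space, "log2fc")) {
      log2fc_profiles(ct, unassigned)
    } else {
      condition_profiles(m, des)[unassigned, , drop = FALSE]
    }
    ok <- apply(prof, 1, function(v) all(is.finite(v)) && stats::sd(v) > 0)
    clus <- cluster_profiles(prof[ok, , drop = FALSE],
                             kmax = config$cluster$kmax,
                             B = config$cluster$B, seed = seed,
                             tau = config$cluster$tau)
    log_stage("cluster", "k = %d clusters over %d proteins",
              length(unique(clus$membership)), sum(ok))
    utils::write.table(data.frame(accession = names(clus$membership),
                                  cluster = clus$membership,
                                  like_group = clus$protein_groups),
                       file.path(out_dir, "clusters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(clus$like_groups,
                       file.path(out_dir, "like_groups.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    log_stage("cluster", "skipped (%d unassigned proteins)",
              length(unassigned))
  }
  # --- correlate ----------------------------------------------------------
  corr <- NULL
  if (!is.null(tx)) {
    rpm <- rpm_normalize(tx)
    corr <- correlate_omics(m, rpm, des, rna_design,
                            cut = config$correlate$cut,
                            pseudocount = config$correlate$pseudocount)
    log_stage("correlate",
              "positive %.1f%%, uncorrelated %.1f%%, negative %.1f%%",
              100 * corr$proportions["positive"],
              100 * corr$proportions["uncorrelated"],
              100 * corr$proportions["negative"])
    utils::write.table(corr$records, file.path(out_dir, "correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    log_stage("correlate", "skipped (no transcript input)")
  }
  # --- manifest -----------------------------------------------------------
  n_unassigned <- length(unassigned)
  stopifnot(n_classified + n_unassigned == length(dap))
  manifest <- list(
    config = config,
    seed = seed,
    rules_hash = rules_hash(rules),
    counts = list(proteins_in = nrow(raw), proteins_tested = nrow(m),
                  daps = length(dap), classified = n_classified,
                  unassigned = n_unassigned,
                  clustered = if (!is.null(clus)) length(clus$membership)
                              else 0L),
    contrast_summary = cs,
    correlation_skipped = is.null(corr),
    group_summary = attr(ka, "summary"),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  tmp <- tempfile(tmpdir = out_dir)
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  file.rename(tmp, file.path(out_dir, "manifest.json"))
  invisible(list(abundance = m, design = des, contrasts = ct,
                 assignments = ka, clustering = clus, correlation = corr,
                 truth = truth, qc = qc, manifest = manifest))
}
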