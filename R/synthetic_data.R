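#' Simulation configuration
#'
#' Describes a synthetic nuclear-proteome experiment: planted kinetic
#' classes with known effect profiles, replicate noise, left-censored plus
#' completely-at-random missingness, and a matched negative-binomial
#' transcriptome with tunable protein-mRNA coupling.
#'
#' Defaults emulate the structure of the real experiment: 3 replicates per
#' condition, around 2,800 proteins, mostly unchanged (NULL class), planted
#' classes at effect size 2 log2 units with replicate noise 0.3 log2 units,
#' baseline log2 intensity Normal(20, 2), 5% left-censoring plus 2% MCAR.
#'
#' @param n_per_class named integer vector of proteins per class over
#'   \{EG, LG, TG, EPG, LPG, RG, CG, NULL\}.
#' @param prob_up probability a planted protein's direction is +1
#'   (default 0.8: most planted proteins accumulate under heat).
#' @param delta effect size in log2 units (default 2).
#' @param sigma replicate noise sd in log2 units (default 0.3).
#' @param baseline_mean,baseline_sd log2 baseline intensity distribution
#'   (default Normal(20, 2)).
#' @param n_replicates replicates per condition (default 3).
#' @param lod_quantile per-sample quantile below which intensities are
#'   censored (default 0.05).
#' @param mcar_rate additional missing-completely-at-random rate
#'   (default 0.02).
#' @param rho protein-mRNA coupling in \[0, 1\]: either a single value for
#'   every gene (default 0.7) or a named vector per class.
#' @param nb_dispersion negative-binomial dispersion of transcript counts
#'   (default 0.05).
#' @param library_size mean sequencing depth per sample (default 2e7).
#' @param seed integer seed (mandatory; all randomness flows from it).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_per_class = c(EG = 100, LG = 100, TG = 100,
                                       EPG = 100, LPG = 100, RG = 100,
                                       CG = 100, "NULL" = 2100),
                       prob_up = 0.8, delta = 2, sigma = 0.3,
                       baseline_mean = 20, baseline_sd = 2,
                       n_replicates = 3, lod_quantile = 0.05,
                       mcar_rate = 0.02, rho = 0.7,
                       nb_dispersion = 0.05, library_size = 2e7,
                       seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(sigma >= 0, delta > 0, n_replicates >= 2,
            lod_quantile >= 0, lod_quantile <= 1,
            mcar_rate >= 0, mcar_rate <= 1,
            prob_up >= 0, prob_up <= 1,
            all(rho >= 0), all(rho <= 1))
  known <- c("EG", "LG", "TG", "EPG", "LPG", "RG", "CG", "NULL")
  bad <- setdiff(names(n_per_class), known)
  if (length(bad)) stop("unknown class(es): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(n_per_class = n_per_class, prob_up = prob_up,
                 delta = delta, sigma = sigma,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 n_replicates = n_replicates, lod_quantile = lod_quantile,
                 mcar_rate = mcar_rate, rho = rho,
                 nb_dispersion = nb_dispersion,
                 library_size = library_size, seed = as.integer(seed)),
            class = "sim_config")
}

#' Per-class mean offset profiles
#'
#' Offsets (log2 units) relative to baseline, order (T22, H4, H24, R22),
#' for direction +1: EG rises early and is restored in recovery; LG rises
#' late; TG rises transiently at 4 h; EPG and LPG persist through
#' recovery; RG changes only in the recovery phase; CG climbs continuously;
#' NULL is flat. Direction -1 negates the offsets.
#'
#' @param delta effect size in log2 units.
#' @return Named list of numeric 4-vectors.
#' @export
class_mean_profiles <- function(delta = 2) {
  stopifnot(delta > 0)
  list(EG  = c(0, delta, delta, 0),
       LG  = c(0, 0, delta, 0),
       TG  = c(0, delta, 0, 0),
       EPG = c(0, delta, delta, delta),
       LPG = c(0, 0, delta, delta),
       RG  = c(0, 0, 0, delta),
       CG  = c(0, delta / 3, 2 * delta / 3, delta),
       "NULL" = c(0, 0, 0, 0))
}

#' Default design of the simulated experiment
#'
#' @param n_replicates replicates per condition.
#' @return A `sample_design`: samples named `<condition>_r<replicate>`.
#' @export
simulate_design <- function(n_replicates = 3) {
  conds <- conditions()
  sample_design(
    sample = paste0(rep(conds, each = n_replicates), "_r",
                    rep(seq_len(n_replicates), length(conds))),
    condition = rep(conds, each = n_replicates),
    replicate = rep(seq_len(n_replicates), length(conds))
  )
}

#' Simulate a nuclear proteome with planted kinetic classes
#'
#' Per protein: log2 value = baseline + class offset (times direction) +
#' Normal(0, sigma^2) per replicate; intensity = 2^value. A value goes
#' missing when it falls below the per-sample `lod_quantile` of realized
#' log2 intensities (left censoring) or by an MCAR coin flip. Fully
#' reproducible given the config seed.
#'
#' @param cfg a `sim_config`.
#' @return List: `abundance` (`abundance_matrix`, raw scale), `truth`
#'   (data frame: accession, class, direction, mu_T22..mu_R22), `design`.
#' @export
simulate_proteome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  design <- simulate_design(cfg$n_replicates)
  profiles <- class_mean_profiles(cfg$delta)
  classes <- rep(names(cfg$n_per_class), cfg$n_per_class)
  n <- length(classes)
  with_seed(cfg$seed, {
    direction <- ifelse(classes == "NULL", 0L,
                        ifelse(stats::runif(n) < cfg$prob_up, 1L, -1L))
    baseline <- stats::rnorm(n, cfg$baseline_mean, cfg$baseline_sd)
    offs <- t(vapply(seq_len(n), function(i) {
      profiles[[classes[i]]] * ifelse(direction[i] == 0, 1, direction[i])
    }, numeric(4)))
    mu <- baseline + offs                      # n x 4 true log2 means
    cond_of <- match(design$condition, conditions())
    vals <- mu[, cond_of] +
      matrix(stats::rnorm(n * nrow(design), 0, cfg$sigma), n)
    rownames(vals) <- sprintf("P%05d", seq_len(n))
    colnames(vals) <- design$sample
    # left censoring at the per-sample LOD quantile, then MCAR
    for (j in seq_len(ncol(vals))) {
      lod <- stats::quantile(vals[, j], probs = cfg$lod_quantile,
                             names = FALSE)
      vals[vals[, j] < lod, j] <- NA_real_
    }
    if (cfg$mcar_rate > 0) {
      vals[matrix(stats::runif(length(vals)) < cfg$mcar_rate,
                  nrow(vals))] <- NA_real_
    }
    truth <- data.frame(accession = rownames(vals), class = classes,
                        direction = direction,
                        mu_T22 = mu[, 1], mu_H4 = mu[, 2],
                        mu_H24 = mu[, 3], mu_R22 = mu[, 4],
                        stringsAsFactors = FALSE)
    list(abundance = abundance_matrix(2^vals, scale = "raw"),
         truth = truth, design = design)
  })
}

#' Split protein intensities into peptide rows
#'
#' Optional peptide-level view: each protein spawns 1-10 peptides whose
#' abundances sum exactly to the protein intensity in every sample (missing
#' protein values give missing peptides), to exercise peptide aggregation.
#'
#' @param proteome result of [simulate_proteome()].
#' @param max_peptides maximum peptides per protein (default 10).
#' @param seed integer seed.
#' @return Peptide data frame (`peptide_id`, `accession`, one column per
#'   sample).
#' @export
simulate_peptides <- function(proteome, max_peptides = 10, seed = 1) {
  m <- proteome$abundance
  with_seed(seed, {
    npep <- sample.int(max_peptides, nrow(m), replace = TRUE)
    rows <- lapply(seq_len(nrow(m)), function(i) {
      k <- npep[i]
      w <- stats::runif(k)
      w <- w / sum(w)
      pep <- outer(w, unclass(m)[i, ])
      data.frame(peptide_id = sprintf("%s_pep%02d", rownames(m)[i], 1:k),
                 accession = rownames(m)[i], pep,
                 check.names = FALSE, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate matched transcript counts
#'
#' Per gene, the latent 4-condition log2 expression profile is
#' rho * (standardized protein true profile) + sqrt(1 - rho^2) * independent
#' standard-normal profile noise; counts per replicate are negative
#' binomial with mean library_size * base_expr * 2^(amplitude * latent) /
#' normalizer. NULL-class genes (flat protein profile) get pure noise
#' profiles.
#'
#' @param truth truth table from [simulate_proteome()].
#' @param cfg a `sim_config`.
#' @param amplitude log2 swing applied to the standardized latent profile
#'   (default 1).
#' @return List: `counts` (a `transcript_counts`; totals = column sums),
#'   `design` (RNA sample design, same layout), `rho` (per-gene target
#'   coupling).
#' @export
simulate_transcripts <- function(truth, cfg, amplitude = 1) {
  design <- simulate_design(cfg$n_replicates)
  n <- nrow(truth)
  rho <- if (length(cfg$rho) == 1) rep(cfg$rho, n) else {
    unname(cfg$rho[truth$class])
  }
  rho[is.na(rho)] <- 0
  mu_prot <- as.matrix(truth[, c("mu_T22", "mu_H4", "mu_H24", "mu_R22")])
  with_seed(cfg$seed + 1L, {
    zprot <- t(apply(mu_prot, 1, function(v) {
      s <- stats::sd(v)
      if (s == 0) rep(0, 4) else (v - mean(v)) / s
    }))
    znoise <- matrix(stats::rnorm(n * 4), n)
    znoise <- t(apply(znoise, 1, function(v) (v - mean(v)) / stats::sd(v)))
    latent <- rho * zprot + sqrt(1 - rho^2) * znoise
    base_expr <- 2^stats::rnorm(n, 4, 1.5)     # relative expression levels
    rel <- base_expr * 2^(amplitude * latent)  # n x 4
    cond_of <- match(design$condition, conditions())
    mu <- rel[, cond_of]
    mu <- sweep(mu, 2, colSums(mu), "/") * cfg$library_size
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / cfg$nb_dispersion),
                     nrow = n)
    rownames(counts) <- truth$accession
    colnames(counts) <- design$sample
    list(counts = transcript_counts(counts), design = design, rho = rho)
  })
}

#' Evaluate recovery of planted classes
#'
#' Compares pipeline assignments with the planted truth: per-class
#' precision and recall over the six kinetic groups, overall accuracy on
#' planted kinetic-class proteins, the realized false-discovery proportion
#' of the differential stage (NULL proteins in the DAP set), and the
#' confusion matrix.
#'
#' @param assignments a `kinetic_assignment` (accession, group, direction).
#' @param truth truth table from [simulate_proteome()].
#' @param dap optional character vector: the DAP set (defaults to the
#'   assigned accessions).
#' @return List: `accuracy`, `per_class` (precision/recall), `fdp_dap`,
#'   `confusion`.
#' @export
evaluate_recovery <- function(assignments, truth, dap = NULL) {
  if (is.null(dap)) dap <- assignments$accession
  planted <- truth$class
  names(planted) <- truth$accession
  assigned <- rep("UNASSIGNED", nrow(truth))
  names(assigned) <- truth$accession
  assigned[assignments$accession] <- assignments$group
  kin <- kinetic_groups()
  lev <- c(kin, "CG", "NULL")
  confusion <- table(planted = factor(planted, lev),
                     assigned = factor(assigned,
                                       c(kin, "UNASSIGNED")))
  is_kin <- planted %in% kin
  accuracy <- mean(assigned[is_kin] == planted[is_kin])
  per_class <- do.call(rbind, lapply(kin, function(g) {
    tp <- sum(planted == g & assigned == g)
    data.frame(class = g,
               precision = if (sum(assigned == g)) tp / sum(assigned == g)
                           else NA_real_,
               recall = tp / sum(planted == g),
               stringsAsFactors = FALSE)
  }))
  null_acc <- truth$accession[planted == "NULL"]
  fdp_dap <- if (length(dap)) sum(dap %in% null_acc) / length(dap) else 0
  list(accuracy = accuracy, per_class = per_class, fdp_dap = fdp_dap,
       confusion = confusion)
}

#' Write a full simulated dataset to TSV files
#'
#' @param cfg a `sim_config`.
#' @param out_prefix path prefix; writes `<prefix>_design.tsv`,
#'   `<prefix>_proteins.tsv`, `<prefix>_counts.tsv`, `<prefix>_totals.tsv`,
#'   `<prefix>_truth.tsv` (and `<prefix>_peptides.tsv` when `peptides`).
#' @param peptides also write the peptide-level table (default FALSE).
#' @return Invisibly, the named vector of file paths.
#' @export
write_simulation <- function(cfg, out_prefix, peptides = FALSE) {
  sim <- simulate_proteome(cfg)
  tx <- simulate_transcripts(sim$truth, cfg)
  paths <- c(design = paste0(out_prefix, "_design.tsv"),
             proteins = paste0(out_prefix, "_proteins.tsv"),
             counts = paste0(out_prefix, "_counts.tsv"),
             totals = paste0(out_prefix, "_totals.tsv"),
             truth = paste0(out_prefix, "_truth.tsv"))
  write_design(sim$design, paths["design"])
  write_abundance(sim$abundance, paths["proteins"])
  cts <- tx$counts
  utils::write.table(data.frame(accession = rownames(cts$counts),
                                cts$counts, check.names = FALSE),
                     paths["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(data.frame(sample = names(cts$totals),
                                total_mapped_reads = cts$totals),
                     paths["totals"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- sim$truth
  truth$rho <- tx$rho
  utils::write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (peptides) {
    p <- paste0(out_prefix, "_peptides.tsv")
    utils::write.table(simulate_peptides(sim, seed = cfg$seed + 2L), p,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    paths <- c(paths, peptides = p)
  }
  invisible(paths)
}
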