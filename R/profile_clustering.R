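#' Per-condition abundance profiles
#'
#' Summarizes each protein as its per-condition mean log2 abundance in the
#' fixed order T22, H4, H24, R22, optionally z-standardized per protein
#' (mean 0, unit variance). Constant profiles cannot be z-scored or enter a
#' Pearson distance; they are set to all-zero and flagged.
#'
#' @param m an `abundance_matrix` on log2 scale.
#' @param design a `sample_design`.
#' @param standardize z-score each profile (default TRUE).
#' @return Numeric matrix proteins x 4 with attribute `constant` (logical
#'   flag per protein).
#' @export
condition_profiles <- function(m, design, standardize = TRUE) {
  if (abundance_scale(m) != "log2") stop("profiles require log2 scale",
                                         call. = FALSE)
  conds <- conditions()
  prof <- sapply(conds, function(cc) {
    s <- design$sample[design$condition == cc]
    rowMeans(m[, s, drop = FALSE], na.rm = TRUE)
  })
  prof[is.nan(prof)] <- NA_real_
  constant <- apply(prof, 1, function(v) {
    all(is.finite(v)) && stats::sd(v) == 0
  }) | apply(prof, 1, function(v) any(!is.finite(v)))
  if (standardize) {
    mu <- rowMeans(prof)
    sd <- apply(prof, 1, stats::sd)
    prof <- (prof - mu) / sd
    prof[constant, ] <- 0
  }
  attr(prof, "constant") <- constant
  prof
}

#' Profiles in log2 fold-change space
#'
#' Alternate clustering representation: each protein as its 6-vector of
#' log2 fold changes over the canonical contrasts.
#'
#' @param ct a `contrast_table`.
#' @param accessions optional subset of accessions.
#' @return Numeric matrix proteins x 6 (columns C1..C6).
#' @export
log2fc_profiles <- function(ct, accessions = NULL) {
  ids <- paste0("C", 1:6)
  accs <- unique(ct$accession)
  if (!is.null(accessions)) accs <- intersect(accs, accessions)
  m <- matrix(NA_real_, length(accs), 6, dimnames = list(accs, ids))
  keep <- ct$accession %in% accs
  m[cbind(match(ct$accession[keep], accs), match(ct$contrast[keep], ids))] <-
    ct$log2fc[keep]
  m
}

#' Pearson correlation distance
#'
#' d(i, j) = 1 - r(i, j) with r the Pearson correlation between the two
#' profile vectors; symmetric, zero diagonal, values in \[0, 2\]. Constant
#' profiles have no defined correlation and are excluded with a warning.
#'
#' @param profiles numeric matrix, one profile per row.
#' @return Symmetric distance matrix with attribute `excluded` (rownames of
#'   dropped constant profiles).
#' @export
pearson_distance <- function(profiles) {
  if (nrow(profiles) < 2) stop("need at least 2 profiles", call. = FALSE)
  constant <- apply(profiles, 1, function(v) stats::sd(v) == 0 || any(!is.finite(v)))
  excluded <- rownames(profiles)[constant]
  if (any(constant)) {
    warning("excluding ", sum(constant), " constant profile(s)")
    profiles <- profiles[!constant, , drop = FALSE]
  }
  r <- stats::cor(t(profiles))
  d <- 1 - r
  diag(d) <- 0
  d[d < 0] <- 0
  d[d > 2] <- 2
  attr(d, "excluded") <- excluded
  d
}

#' Complete-linkage agglomerative clustering
#'
#' Builds the merge tree in which the distance between two clusters is the
#' maximum pairwise distance between their members. Ties are broken
#' deterministically by the smallest original member index. The result is
#' hclust-compatible (`merge`, `height`, `order`, `labels`).
#'
#' @param d symmetric distance matrix.
#' @return A `linkage_tree` (also of class `hclust`).
#' @export
complete_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 items", call. = FALSE)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  D <- d
  diag(D) <- Inf
  active <- rep(TRUE, n)
  node <- -seq_len(n)         # hclust convention: negative = singleton
  minidx <- seq_len(n)        # smallest original index per cluster
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    h <- min(sub)
    # all tied pairs at the minimum; break by smallest member index, then
    # by the partner's smallest member index
    w <- which(sub == h, arr.ind = TRUE)
    w <- w[w[, 1] < w[, 2], , drop = FALSE]
    a <- idx[w[, 1]]; b <- idx[w[, 2]]
    lo <- pmin(minidx[a], minidx[b]); hi <- pmax(minidx[a], minidx[b])
    pick <- order(lo, hi)[1]
    i <- a[pick]; j <- b[pick]
    merge[step, ] <- sort(c(node[i], node[j]))
    height[step] <- h
    # complete-linkage Lance-Williams update: new distance = max
    upd <- pmax(D[i, ], D[j, ])
    D[i, ] <- upd
    D[, i] <- upd
    D[i, i] <- Inf
    active[j] <- FALSE
    D[j, ] <- Inf
    D[, j] <- Inf
    node[i] <- step
    minidx[i] <- min(minidx[i], minidx[j])
  }
  tree <- structure(list(merge = merge, height = height,
                         order = .leaf_order(merge, n),
                         labels = labels, method = "complete",
                         dist.method = "pearson"),
                    class = c("linkage_tree", "hclust"))
  tree
}

# leaf order by in-order traversal of the merge tree (hclust 'order' slot)
.leaf_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(n - 1L)
}

#' Cut a linkage tree into k clusters
#'
#' Undoes the last k - 1 merges. Cluster labels 1..k follow dendrogram
#' leaf order (the heatmap row order), so label 1 is the cluster of the
#' left-most leaf.
#'
#' @param tree a `linkage_tree`.
#' @param k number of clusters, 1 <= k <= n.
#' @return Named integer vector of cluster memberships.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$labels)
  if (k < 1 || k > n) stop("k out of range [1, ", n, "]", call. = FALSE)
  memb <- stats::cutree(tree, k = k)
  # relabel by first appearance in leaf order
  ord <- tree$order
  first <- unique(memb[ord])
  memb <- match(memb, first)
  names(memb) <- tree$labels
  memb
}

# within-cluster dispersion W_k = sum_r D_r / (2 n_r), D_r the sum of
# pairwise squared distances within cluster r
.wk <- function(d2, memb) {
  w <- 0
  for (cl in unique(memb)) {
    ix <- which(memb == cl)
    if (length(ix) > 1) {
      w <- w + sum(d2[ix, ix]) / (2 * length(ix))
    }
  }
  w
}

#' Gap statistic for the number of clusters
#'
#' For each k in 1..kmax computes the within-cluster dispersion
#' W_k = sum over clusters of (sum of pairwise squared Pearson distances) /
#' (2 cluster size) of the complete-linkage partition, and compares
#' log(W_k) with its mean over B reference datasets drawn uniformly over
#' each feature's observed range (clustered the same way).
#' gap_k = mean_b log(W_k^(b)) - log(W_k);
#' se_k = sd_b(log W_k^(b)) * sqrt(1 + 1/B).
#'
#' Two selection rules are provided. The default, `"firstSEmax"` (the rule
#' of the same name in `cluster::clusGap` and the factoextra default),
#' locates the first local maximum f of the gap curve and returns the
#' smallest k with gap_k >= gap_f - se_f. `"Tibs2001SEmax"` is the original
#' sequential rule: the smallest k with gap_k >= gap_(k+1) - se_(k+1)
#' (kmax if none qualifies). The sequential rule can stop at an early
#' plateau well short of clearly separated structure; see the methods
#' vignette.
#'
#' @param profiles numeric matrix, one profile per row.
#' @param kmax maximum number of clusters (< number of profiles).
#' @param B number of reference datasets (>= 10; default 100).
#' @param seed integer seed for the reference draws.
#' @param rule selection rule, `"firstSEmax"` (default) or
#'   `"Tibs2001SEmax"`.
#' @return A `gap_statistic` list: data frame `table` (k, W_k, log_Wk,
#'   E_log_Wk, gap, se), `k` (chosen), `B`, `seed`, `rule`, and the
#'   `tree` used.
#' @export
gap_statistic <- function(profiles, kmax, B = 100, seed = 1,
                          rule = c("firstSEmax", "Tibs2001SEmax")) {
  rule <- match.arg(rule)
  n <- nrow(profiles)
  if (kmax >= n) stop("kmax must be < number of profiles", call. = FALSE)
  if (B < 10) stop("B must be >= 10", call. = FALSE)
  logw_of <- function(x) {
    d <- pearson_distance(x)
    tr <- complete_linkage(d)
    d2 <- d^2
    vapply(seq_len(kmax), function(k) {
      w <- .wk(d2, cut_tree(tr, k))
      log(max(w, .Machine$double.xmin))
    }, 0)
  }
  d <- pearson_distance(profiles)
  tree <- complete_linkage(d)
  d2 <- d^2
  log_wk <- vapply(seq_len(kmax), function(k) {
    log(max(.wk(d2, cut_tree(tree, k)), .Machine$double.xmin))
  }, 0)
  lo <- apply(profiles, 2, min)
  hi <- apply(profiles, 2, max)
  ref <- with_seed(seed, {
    replicate(B, {
      x <- sapply(seq_along(lo), function(j) stats::runif(n, lo[j], hi[j]))
      logw_of(x)
    })
  })
  ref <- matrix(ref, nrow = kmax)     # kmax x B
  e_log <- rowMeans(ref)
  se <- apply(ref, 1, stats::sd) * sqrt(1 + 1 / B)
  gap <- e_log - log_wk
  if (rule == "Tibs2001SEmax") {
    k_hat <- kmax
    for (k in seq_len(kmax - 1)) {
      if (gap[k] >= gap[k + 1] - se[k + 1]) { k_hat <- k; break }
    }
  } else {
    f <- kmax
    for (k in seq_len(kmax - 1)) {
      if (gap[k] >= gap[k + 1]) { f <- k; break }
    }
    k_hat <- which(gap >= gap[f] - se[f])[1]
  }
  structure(list(table = data.frame(k = seq_len(kmax), W_k = exp(log_wk),
                                    log_Wk = log_wk, E_log_Wk = e_log,
                                    gap = gap, se = se),
                 k = k_hat, B = B, seed = seed, rule = rule, tree = tree),
            class = "gap_statistic")
}

#' Canonical like-group templates
#'
#' Idealized 4-condition shapes (order T22, H4, H24, R22) for matching
#' cluster centroids: early (0,1,1,0), early-persistent (0,1,1,1),
#' late (0,0,1,0), late-persistent (0,0,1,1), transient (0,1,0,0),
#' recovery (0,0,0,1), continuous (0,1/3,2/3,1).
#'
#' @return Named list of numeric 4-vectors.
#' @export
default_templates <- function() {
  list(early = c(0, 1, 1, 0),
       early_persistent = c(0, 1, 1, 1),
       late = c(0, 0, 1, 0),
       late_persistent = c(0, 0, 1, 1),
       transient = c(0, 1, 0, 0),
       recovery = c(0, 0, 0, 1),
       continuous = c(0, 1, 2, 3) / 3)
}

.template_family <- c(early = "ELG", early_persistent = "ELG",
                      late = "LLG", late_persistent = "LLG",
                      transient = "TLG", recovery = "RLG",
                      continuous = "CG")

#' Assign clusters to like-groups
#'
#' Each cluster centroid (mean member profile) is correlated with every
#' template, both orientations considered (|r|). The best-matching template
#' family gives the like-group: early / early-persistent map to ELG,
#' late / late-persistent to LLG, transient to TLG, recovery to RLG,
#' continuous to CG. Centroids matching nothing well (best |r| < tau) are
#' CG when monotone across the four conditions, otherwise keep the best
#' family with a low-confidence flag.
#'
#' @param membership named integer vector of cluster memberships
#'   (accession -> cluster).
#' @param profiles the profile matrix the clusters were built from.
#' @param templates named list of template vectors (default
#'   [default_templates()]).
#' @param tau confidence cutoff on |r| (default 0.8).
#' @return A `like_group_assignment` data frame: `cluster`, `like_group`,
#'   `best_template`, `template_r`, `low_confidence`, `n`.
#' @export
assign_like_groups <- function(membership, profiles,
                               templates = default_templates(), tau = 0.8) {
  accs <- names(membership)
  clusters <- sort(unique(membership))
  rows <- lapply(clusters, function(cl) {
    centroid <- colMeans(profiles[accs[membership == cl], , drop = FALSE])
    if (stats::sd(centroid) == 0) {
      stop("constant centroid in cluster ", cl, call. = FALSE)
    }
    rs <- vapply(templates, function(tp) stats::cor(centroid, tp), 0)
    best <- names(rs)[which.max(abs(rs))]
    best_r <- rs[[best]]
    fam <- .template_family[[best]]
    low <- abs(best_r) < tau
    if (low) {
      dif <- diff(centroid)
      monotone <- all(dif >= 0) || all(dif <= 0)
      if (monotone) {
        fam <- "CG"
        best <- "continuous"
        best_r <- rs[["continuous"]]
        low <- FALSE
      }
    }
    data.frame(cluster = cl, like_group = fam, best_template = best,
               template_r = best_r, low_confidence = low,
               n = sum(membership == cl), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("like_group_assignment", "data.frame")
  out
}

#' Cluster unassigned proteins and assign like-groups
#'
#' The full reclustering stage: Pearson distance on the profiles of the
#' proteins left UNASSIGNED by the rule-based classifier, complete-linkage
#' tree, gap-statistic choice of k, cut, and template matching.
#'
#' @param profiles profile matrix for the unassigned DAPs.
#' @param kmax maximum clusters for the gap statistic (default 12).
#' @param B reference datasets (default 100).
#' @param seed integer seed.
#' @param k optional fixed number of clusters (skips the gap statistic).
#' @param templates,tau passed to [assign_like_groups()].
#' @return List with `membership`, `like_groups`, `gap` (NULL when `k`
#'   fixed), `tree`, and `protein_groups` (accession -> like-group).
#' @export
cluster_profiles <- function(profiles, kmax = 12, B = 100, seed = 1,
                             k = NULL, templates = default_templates(),
                             tau = 0.8) {
  gap <- NULL
  if (is.null(k)) {
    kmax <- min(kmax, nrow(profiles) - 1)
    gap <- gap_statistic(profiles, kmax = kmax, B = B, seed = seed)
    k <- gap$k
    tree <- gap$tree
  } else {
    tree <- complete_linkage(pearson_distance(profiles))
  }
  memb <- cut_tree(tree, k)
  lg <- assign_like_groups(memb, profiles, templates = templates, tau = tau)
  pg <- lg$like_group[match(memb, lg$cluster)]
  names(pg) <- names(memb)
  list(membership = memb, like_groups = lg, gap = gap, tree = tree,
       protein_groups = pg)
}
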