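# Independent oracles used across the suite. Each is a deliberately naive
# re-derivation (loops, textbook formulas) kept separate from the package
# code paths it checks.

# two-pass Pearson correlation: means first, then explicit sums
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# brute-force BH step-up: for each p_i, minimize n p_k / rank_k over all
# p_k >= p_i, by explicit loops
oracle_bh <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(n), function(i) {
    cand <- vapply(seq_len(n), function(k) {
      if (r[k] >= r[i]) n * p[k] / r[k] else Inf
    }, 0)
    min(1, min(cand))
  }, 0)
}

# brute-force complete linkage: clusters as member lists, inter-cluster
# distance recomputed each step as the max over all original pairs,
# ties broken by the smallest original member index
oracle_complete_linkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  partitions <- vector("list", n)   # membership vector at each k
  partitions[[n]] <- seq_len(n)
  for (step in seq_len(n - 1)) {
    m <- length(clusters)
    best <- NULL
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      h <- max(d[clusters[[i]], clusters[[j]]])
      key <- c(h, min(clusters[[i]][1], clusters[[j]][1]),
               max(clusters[[i]][1], clusters[[j]][1]))
      if (is.null(best) || h < best$key[1] - 1e-15 ||
          (abs(h - best$key[1]) <= 1e-15 &&
           (key[2] < best$key[2] ||
            (key[2] == best$key[2] && key[3] < best$key[3])))) {
        best <- list(i = i, j = j, key = key)
      }
    }
    heights[step] <- best$key[1]
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
    memb <- integer(n)
    for (ci in seq_along(clusters)) memb[clusters[[ci]]] <- ci
    partitions[[n - step]] <- memb
  }
  list(heights = heights, partitions = partitions)
}

# canonical partition label: same clustering regardless of label names
canon_partition <- function(memb) {
  match(memb, unique(memb))
}

same_partition <- function(a, b) {
  identical(canon_partition(a), canon_partition(b))
}

# independent transcription of the kinetic group definitions as plain
# boolean tests, bypassing the rule-table machinery
oracle_classify <- function(p) {
  for (d in c(1L, -1L)) {
    if (p[1] == d && p[2] == d && p[3] == 0 && p[4] == 0 && p[6] == -d)
      return(list(group = "EG", direction = d))
    if (p[1] == 0 && p[2] == d && p[3] == 0 && p[4] == d && p[6] == -d)
      return(list(group = "LG", direction = d))
    if (p[1] == d && p[2] == 0 && p[3] == 0 && p[4] == -d)
      return(list(group = "TG", direction = d))
    if (p[1] == d && p[2] == d && p[3] == d && p[4] == 0 && p[6] == 0)
      return(list(group = "EPG", direction = d))
    if (p[1] == 0 && p[2] == d && p[3] == d && p[4] == d && p[6] == 0)
      return(list(group = "LPG", direction = d))
    if (p[1] == 0 && p[2] == 0 && p[3] == d && p[4] == 0)
      return(list(group = "RG", direction = d))
  }
  list(group = "UNASSIGNED", direction = 0L)
}

# row-wise z-standardization
scale_rows <- function(m) {
  t(apply(m, 1, function(v) (v - mean(v)) / sd(v)))
}

# all 3^6 = 729 significance patterns
all_patterns <- function() {
  g <- expand.grid(C1 = -1:1, C2 = -1:1, C3 = -1:1,
                   C4 = -1:1, C5 = -1:1, C6 = -1:1)
  as.matrix(g)
}
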