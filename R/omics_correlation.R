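#' Default proteome/transcriptome condition map
#'
#' Pairs each proteome condition with the transcriptome condition it is
#' correlated against. Both tables in this package use the canonical codes,
#' so the default map is the identity; with external data whose RNA-seq
#' timepoints differ (e.g. 5 h vs 4 h at 37 degrees C), the map makes the
#' chosen pairing explicit.
#'
#' @return Named character vector, proteome condition -> RNA condition.
#' @export
default_condition_map <- function() {
  stats::setNames(conditions(), conditions())
}

#' Match protein and transcript condition profiles
#'
#' Computes per-condition replicate means of protein log2 abundance and of
#' log2(rpm + pseudocount) transcript abundance, then joins by shared ids.
#'
#' @param prot an `abundance_matrix` on log2 scale (proteins).
#' @param rna an `abundance_matrix` on rpm scale (transcripts).
#' @param prot_design,rna_design `sample_design` tables for the two assays.
#' @param map condition map (default [default_condition_map()]); must cover
#'   all four proteome conditions.
#' @param id_map optional data frame (`accession`, `gene_id`) translating
#'   protein accessions to gene ids; default: shared ids.
#' @param pseudocount added to rpm before log2 (default 1; set 0 with
#'   `log_rna = FALSE` semantics not needed since rpm > 0 mostly).
#' @param log_rna log2-transform the rna profile (default TRUE).
#' @return A `matched_profiles` list: matrices `protein` and `rna`
#'   (genes x 4, same row order), `n_dropped` (ids absent from either
#'   side), and the `map` used.
#' @export
match_condition_profiles <- function(prot, rna, prot_design, rna_design,
                                     map = default_condition_map(),
                                     id_map = NULL, pseudocount = 1,
                                     log_rna = TRUE) {
  miss <- setdiff(conditions(), names(map))
  if (length(miss)) {
    stop("condition map missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  pprof <- sapply(conditions(), function(cc) {
    s <- prot_design$sample[prot_design$condition == cc]
    rowMeans(prot[, s, drop = FALSE], na.rm = TRUE)
  })
  rvals <- if (log_rna) log2(unclass(rna) + pseudocount) else unclass(rna)
  rprof <- sapply(conditions(), function(cc) {
    s <- rna_design$sample[rna_design$condition == map[[cc]]]
    rowMeans(rvals[, s, drop = FALSE], na.rm = TRUE)
  })
  pid <- rownames(prot)
  gid <- rownames(rna)
  if (!is.null(id_map)) {
    gene_of <- stats::setNames(id_map$gene_id, id_map$accession)
    keep <- pid %in% names(gene_of) & unname(gene_of[pid]) %in% gid
    shared_p <- pid[keep]
    shared_g <- unname(gene_of[shared_p])
  } else {
    shared_p <- intersect(pid, gid)
    shared_g <- shared_p
  }
  if (!length(shared_p)) stop("no shared ids between proteome and transcriptome",
                              call. = FALSE)
  pp <- pprof[shared_p, , drop = FALSE]
  rr <- rprof[shared_g, , drop = FALSE]
  rownames(rr) <- shared_p
  structure(list(protein = pp, rna = rr,
                 n_dropped = length(pid) - length(shared_p), map = map),
            class = "matched_profiles")
}

#' Per-gene protein-mRNA Pearson correlation
#'
#' Standard Pearson r over the four matched condition points. Correlations
#' on 4 points are noisy by construction; this mirrors the experimental
#' design, not a statistical recommendation. Genes with a constant profile
#' on either side have no defined correlation: r is `NA` and they fall into
#' the uncorrelated category by convention.
#'
#' @param matched a `matched_profiles` object.
#' @return Data frame `gene_id`, `r`.
#' @export
profile_correlations <- function(matched) {
  n <- nrow(matched$protein)
  r <- vapply(seq_len(n), function(i) {
    x <- matched$protein[i, ]; y <- matched$rna[i, ]
    if (any(!is.finite(x)) || any(!is.finite(y)) ||
        stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, 0)
  data.frame(gene_id = rownames(matched$protein), r = r,
             stringsAsFactors = FALSE)
}

#' Categorize a correlation coefficient
#'
#' positive for r in \[0.5, 1\], negative for r in \[-1, -0.5\] (symmetric
#' cut), else uncorrelated; `NA` (undefined correlation) is uncorrelated by
#' convention. Both boundaries are inclusive.
#'
#' @param r numeric vector in \[-1, 1\] (NA allowed).
#' @param cut absolute cut point (default 0.5).
#' @return Character vector over
#'   \{"positive", "uncorrelated", "negative"\}.
#' @export
categorize_correlation <- function(r, cut = 0.5) {
  stopifnot(all(abs(r) <= 1 + 1e-12, na.rm = TRUE))
  out <- rep("uncorrelated", length(r))
  out[!is.na(r) & r >= cut] <- "positive"
  out[!is.na(r) & r <= -cut] <- "negative"
  out
}

#' Correlation category proportions
#'
#' @param records data frame with columns `gene_id`, `r` (and optionally
#'   `category`; recomputed if absent).
#' @param bins number of histogram bins for the density export
#'   (default 40 over \[-1, 1\]).
#' @return List: `proportions` (named fractions positive / uncorrelated /
#'   negative, summing to 1), `counts`, and `density` (bin mid, count,
#'   density) for plotting export.
#' @export
category_proportions <- function(records, bins = 40) {
  if (!nrow(records)) stop("need at least one record", call. = FALSE)
  cat <- if ("category" %in% names(records)) records$category else
    categorize_correlation(records$r)
  lev <- c("positive", "uncorrelated", "negative")
  counts <- stats::setNames(vapply(lev, function(l) sum(cat == l), 0L), lev)
  props <- counts / sum(counts)
  br <- seq(-1, 1, length.out = bins + 1)
  rr <- pmin(pmax(records$r[!is.na(records$r)], -1), 1)
  bin <- pmin(findInterval(rr, br, rightmost.closed = TRUE), bins)
  cnt <- tabulate(bin, nbins = bins)
  width <- diff(br)
  dens <- data.frame(mid = (br[-1] + br[-(bins + 1)]) / 2, count = cnt,
                     density = if (length(rr)) cnt / (sum(cnt) * width)
                               else rep(0, bins))
  list(proportions = props, counts = counts, density = dens)
}

#' Full correlation stage
#'
#' Match profiles, correlate, categorize, and summarize.
#'
#' @inheritParams match_condition_profiles
#' @param cut category cut point (default 0.5).
#' @return List: `records` (gene_id, r, category), `proportions`,
#'   `density`, `n_dropped`.
#' @export
correlate_omics <- function(prot, rna, prot_design, rna_design,
                            map = default_condition_map(), id_map = NULL,
                            pseudocount = 1, cut = 0.5) {
  matched <- match_condition_profiles(prot, rna, prot_design, rna_design,
                                      map = map, id_map = id_map,
                                      pseudocount = pseudocount)
  rec <- profile_correlations(matched)
  rec$category <- categorize_correlation(rec$r, cut = cut)
  summ <- category_proportions(rec)
  list(records = rec, proportions = summ$proportions,
       density = summ$density, n_dropped = matched$n_dropped)
}
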