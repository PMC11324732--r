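#' Canonical condition codes
#'
#' The four conditions of the heat-stress time course, in temporal order:
#' control at 22 degrees C (`T22`), 4 h at 37 degrees C (`H4`), 24 h at
#' 37 degrees C (`H24`), and recovery at 22 degrees C after heat (`R22`).
#'
#' @return Character vector of length 4.
#' @export
conditions <- function() c("T22", "H4", "H24", "R22")

# built-in case-insensitive aliases for condition labels
.builtin_aliases <- function() {
  c(t22 = "T22", "22" = "T22", "22c" = "T22",
    h4 = "H4", "37c4h" = "H4", "37_4" = "H4",
    h24 = "H24", "37c24h" = "H24", "37_24" = "H24",
    r22 = "R22", "r22c" = "R22")
}

.normalize_condition <- function(x, aliases = NULL) {
  key <- tolower(gsub("[^0-9a-zA-Z]", "", x))
  map <- .builtin_aliases()
  if (!is.null(aliases)) {
    extra <- aliases
    names(extra) <- tolower(gsub("[^0-9a-zA-Z]", "", names(aliases)))
    map <- c(extra, map)
  }
  out <- unname(map[key])
  bad <- is.na(out)
  if (any(bad)) {
    stop("unknown condition label(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " (rows ", paste(which(bad), collapse = ", "), ")",
         call. = FALSE)
  }
  out
}

#' Construct a sample design
#'
#' @param sample character vector of unique sample ids.
#' @param condition character vector of condition labels; resolved onto the
#'   canonical codes [conditions()], case-insensitively, with optional extra
#'   aliases.
#' @param replicate integer vector of replicate indices (>= 1).
#' @param aliases optional named character vector mapping extra condition
#'   labels to canonical codes, e.g. `c("37C_4h" = "H4")`.
#' @return A `sample_design` data frame with columns `sample`, `condition`,
#'   `replicate`.
#' @export
sample_design <- function(sample, condition, replicate, aliases = NULL) {
  sample <- as.character(sample)
  if (anyDuplicated(sample)) {
    stop("duplicate sample_id: ",
         paste(unique(sample[duplicated(sample)]), collapse = ", "),
         call. = FALSE)
  }
  condition <- .normalize_condition(as.character(condition), aliases)
  replicate <- as.integer(replicate)
  if (any(is.na(replicate)) || any(replicate < 1)) {
    stop("replicate must be an integer >= 1", call. = FALSE)
  }
  d <- data.frame(sample = sample, condition = condition,
                  replicate = replicate, stringsAsFactors = FALSE)
  class(d) <- c("sample_design", "data.frame")
  d
}

#' Read a sample design table
#'
#' Expects a delimiter-separated text file with header columns
#' `sample`, `condition`, `replicate`.
#'
#' @param path file path.
#' @param aliases optional named character vector of extra condition aliases.
#' @return A `sample_design` data frame.
#' @export
read_design <- function(path, aliases = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample", "condition", "replicate")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("design file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sample_design(d$sample, d$condition, d$replicate, aliases = aliases)
}

#' Write a sample design table
#' @param design a `sample_design`.
#' @param path output path.
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Construct an abundance matrix
#'
#' The central quantitative container: proteins (or genes) in rows, samples
#' in columns, with explicit missing values and a recorded measurement scale.
#'
#' @param values numeric matrix with unique rownames (accessions) and
#'   colnames (sample ids). `NA` encodes a missing measurement; zero is a
#'   measured zero (only meaningful on `raw`/`rpm` scales).
#' @param scale one of `"raw"`, `"log2"`, `"rpm"`.
#' @return An `abundance_matrix`.
#' @export
abundance_matrix <- function(values, scale = c("raw", "log2", "rpm")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("abundance matrix needs rownames (accessions) and colnames (samples)",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate row keys in abundance matrix", call. = FALSE)
  }
  if (scale != "log2" && any(values < 0, na.rm = TRUE)) {
    stop("negative abundances on ", scale, " scale", call. = FALSE)
  }
  if (any(is.infinite(values))) {
    stop("infinite abundances are not allowed", call. = FALSE)
  }
  structure(values, scale = scale, class = c("abundance_matrix", "matrix", "array"))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d rows x %d samples, scale=%s, %.1f%% missing\n",
              nrow(x), ncol(x), attr(x, "scale"),
              100 * mean(is.na(x))))
  invisible(x)
}

#' Scale of an abundance matrix
#' @param m an `abundance_matrix`.
#' @return `"raw"`, `"log2"`, or `"rpm"`.
#' @export
abundance_scale <- function(m) attr(m, "scale")

# subsetting keeps class and scale
#' @export
`[.abundance_matrix` <- function(x, i, j, ..., drop = TRUE) {
  sc <- attr(x, "scale")
  y <- NextMethod()
  if (is.matrix(y)) {
    structure(y, scale = sc, class = class(x))
  } else y
}

#' Read an abundance table from TSV
#'
#' First column `accession`, remaining columns one per sample id. Empty
#' fields are missing values (never zero).
#'
#' @param path file path.
#' @param scale measurement scale recorded on the result.
#' @return An `abundance_matrix`.
#' @export
read_abundance <- function(path, scale = "raw") {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = c("", "NA"))
  if (names(d)[1] != "accession") {
    stop("abundance file must start with an 'accession' column", call. = FALSE)
  }
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$accession
  abundance_matrix(m, scale = scale)
}

#' Write an abundance table to TSV
#'
#' Missing values become empty fields; values are written with 15
#' significant digits so write/read round-trips to at least 12 digits.
#'
#' @param m an `abundance_matrix`.
#' @param path output path.
#' @export
write_abundance <- function(m, path) {
  d <- data.frame(accession = rownames(m),
                  signif(unclass(m), 15),
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Construct a transcript count table
#'
#' @param counts integer matrix genes x samples, counts >= 0.
#' @param totals named numeric vector of per-sample total mapped reads
#'   (> 0); names must cover the count columns. Defaults to column sums.
#' @return A `transcript_counts` object (list with `counts`, `totals`).
#' @export
transcript_counts <- function(counts, totals = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE) || any(counts != round(counts), na.rm = TRUE)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (is.null(names(totals))) names(totals) <- colnames(counts)
  totals <- totals[colnames(counts)]
  if (any(is.na(totals)) || any(totals <= 0)) {
    stop("total_mapped_reads must be strictly positive for every sample",
         call. = FALSE)
  }
  over <- colSums(counts) > totals + 1e-8
  if (any(over)) {
    stop("assigned counts exceed total_mapped_reads for sample(s): ",
         paste(colnames(counts)[over], collapse = ", "), call. = FALSE)
  }
  structure(list(counts = counts, totals = totals),
            class = "transcript_counts")
}

#' Read transcript counts and totals
#'
#' @param counts_path TSV with first column `accession` (gene id) and one
#'   column per sample.
#' @param totals_path optional 2-column TSV `sample`, `total_mapped_reads`;
#'   when omitted, totals default to the column sums.
#' @return A `transcript_counts` object.
#' @export
read_transcript_counts <- function(counts_path, totals_path = NULL) {
  d <- utils::read.delim(counts_path, stringsAsFactors = FALSE,
                         check.names = FALSE, na.strings = c("", "NA"))
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  if (is.null(totals_path)) return(transcript_counts(m))
  t <- utils::read.delim(totals_path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  totals <- t$total_mapped_reads
  names(totals) <- t$sample
  transcript_counts(m, totals)
}

#' Aggregate peptide abundances to protein abundances
#'
#' Protein abundance in a sample is the sum of that protein's observed
#' peptide abundances in that sample (no scaling by peptide count). If all
#' peptides of a protein are missing in a sample, the protein value is
#' missing, not zero.
#'
#' @param peptides data frame with columns `peptide_id`, `accession`, then
#'   one numeric column per sample (raw linear scale; `NA` = missing).
#' @param design a `sample_design`; every sample column must appear in it.
#' @return An `abundance_matrix` on `raw` scale.
#' @export
aggregate_peptides <- function(peptides, design) {
  need <- c("peptide_id", "accession")
  if (!all(need %in% names(peptides))) {
    stop("peptide table needs columns peptide_id, accession", call. = FALSE)
  }
  acc <- as.character(peptides$accession)
  if (any(is.na(acc) | acc == "")) {
    stop("peptide mapped to empty protein accession", call. = FALSE)
  }
  samp_cols <- setdiff(names(peptides), need)
  missing_design <- setdiff(samp_cols, design$sample)
  if (length(missing_design)) {
    stop("peptide sample column(s) absent from design: ",
         paste(missing_design, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(peptides[, samp_cols, drop = FALSE])
  if (any(x < 0, na.rm = TRUE)) {
    stop("negative peptide abundances", call. = FALSE)
  }
  obs <- !is.na(x)
  x0 <- x
  x0[!obs] <- 0
  sums <- rowsum(x0, acc)                # observed contributions
  nobs <- rowsum(obs + 0, acc)           # observed peptide counts
  sums[nobs == 0] <- NA_real_            # all-missing propagates
  abundance_matrix(sums, scale = "raw")
}

#' Reads-per-million normalization
#'
#' @param tc a `transcript_counts` object.
#' @return An `abundance_matrix` on `rpm` scale:
#'   count / total_mapped_reads x 1e6.
#' @export
rpm_normalize <- function(tc) {
  stopifnot(inherits(tc, "transcript_counts"))
  rpm <- sweep(tc$counts, 2, tc$totals, "/") * 1e6
  abundance_matrix(rpm, scale = "rpm")
}

#' Log2 transform an abundance matrix
#'
#' Positive values are log2-transformed; zeros are treated as censored and
#' become missing (a zero intensity is below the detection limit, not an
#' abundance of 2^0).
#'
#' @param m an `abundance_matrix` on `raw` or `rpm` scale.
#' @param pseudocount optional value added before the log (default 0); with
#'   a positive pseudocount zeros stay finite.
#' @return An `abundance_matrix` on `log2` scale.
#' @export
log2_transform <- function(m, pseudocount = 0) {
  if (abundance_scale(m) == "log2") {
    stop("matrix is already on log2 scale", call. = FALSE)
  }
  if (any(m < 0, na.rm = TRUE)) stop("negative input", call. = FALSE)
  v <- unclass(m) + pseudocount
  v[v == 0] <- NA_real_
  abundance_matrix(log2(v), scale = "log2")
}

# per-condition observation counts, proteins x conditions
.condition_obs_counts <- function(m, design) {
  conds <- intersect(conditions(), unique(design$condition))
  out <- sapply(conds, function(cc) {
    s <- design$sample[design$condition == cc]
    rowSums(!is.na(m[, s, drop = FALSE]))
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(m),
                                       dimnames = list(rownames(m), conds))
  out
}

#' Presence filter
#'
#' Retains proteins with at least `min_per_condition` observed values in at
#' least one condition (`mode = "global"`). Per-contrast testability (at
#' least `min_per_condition` observed in both conditions of a contrast) is
#' enforced downstream by [run_contrasts()]; this function records the
#' chosen mode so runs are self-describing.
#'
#' @param m an `abundance_matrix`.
#' @param design a `sample_design`.
#' @param min_per_condition minimum observed replicates (default 2 of 3).
#' @param mode `"global"` (filter now) or `"per_contrast"` (defer; matrix
#'   returned unchanged with the mode recorded).
#' @return The filtered `abundance_matrix`, with attributes `filter_mode`
#'   and `min_per_condition`.
#' @export
presence_filter <- function(m, design, min_per_condition = 2,
                            mode = c("global", "per_contrast")) {
  mode <- match.arg(mode)
  if (min_per_condition > max(table(design$condition))) {
    stop("min_per_condition exceeds the replicate count", call. = FALSE)
  }
  out <- m
  if (mode == "global" && min_per_condition > 0) {
    keep <- apply(.condition_obs_counts(m, design) >= min_per_condition, 1, any)
    out <- m[keep, , drop = FALSE]
  }
  attr(out, "filter_mode") <- mode
  attr(out, "min_per_condition") <- min_per_condition
  out
}

#' Left-censored imputation of missing log2 intensities
#'
#' Replaces each missing value by a draw from a normal distribution centred
#' at a low per-sample quantile of the observed log2 intensities, emulating
#' values just below the detection limit. Off by default in the pipeline:
#' statistics use available-case analysis per contrast.
#'
#' @param m an `abundance_matrix` on `log2` scale.
#' @param quantile per-sample quantile giving the imputation centre
#'   (default 0.01).
#' @param sd spread of the imputation distribution in log2 units
#'   (default 0.3).
#' @param seed integer seed; imputation is reproducible.
#' @return A fully observed `abundance_matrix` on `log2` scale.
#' @export
impute_left_censored <- function(m, quantile = 0.01, sd = 0.3, seed) {
  if (abundance_scale(m) != "log2") stop("imputation requires log2 scale",
                                         call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  nobs <- colSums(!is.na(m))
  if (any(nobs < 10)) {
    stop("sample(s) with < 10 observed values: ",
         paste(colnames(m)[nobs < 10], collapse = ", "), call. = FALSE)
  }
  v <- unclass(m)
  with_seed(seed, {
    for (j in seq_len(ncol(v))) {
      miss <- is.na(v[, j])
      if (!any(miss)) next
      centre <- stats::quantile(v[, j], probs = quantile, na.rm = TRUE,
                                names = FALSE)
      v[miss, j] <- stats::rnorm(sum(miss), mean = centre, sd = sd)
    }
  })
  abundance_matrix(v, scale = "log2")
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so
#' seeded operations leave no hidden global state behind.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
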