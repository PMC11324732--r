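#' The six major kinetic groups
#'
#' EG (early), LG (late), TG (transient), EPG (early persistent),
#' LPG (late persistent), RG (recovery): labels describing when a protein's
#' nuclear abundance changes relative to heat-stress onset and recovery.
#'
#' @return Character vector of the six group codes.
#' @export
kinetic_groups <- function() c("EG", "LG", "TG", "EPG", "LPG", "RG")

#' Default decision rules for kinetic classification
#'
#' One rule per group, expressed as per-contrast tokens over the six
#' significance calls C1..C6 for a candidate direction `d` in \{+1, -1\}:
#' `"d"` requires the call to equal `d`, `"-d"` requires `-d`, `"0"`
#' requires no significant change, `"*"` is a wildcard. The table encodes,
#' for increasing proteins (d = +1):
#' \describe{
#'   \item{EG}{up early (C1, C2), back to baseline in recovery (C3 = 0,
#'     C6 = down).}
#'   \item{LG}{stable at 4 h, up by 24 h (C2, C4), restored in recovery.}
#'   \item{TG}{up at 4 h only, back down by 24 h.}
#'   \item{EPG}{up early and persisting through recovery (C3 = d, C6 = 0).}
#'   \item{LPG}{up late and persisting through recovery.}
#'   \item{RG}{no change during heat, change only in the recovery phase
#'     (C3 = d).}
#' }
#' C5 (R22 vs H4) is unconstrained by default. First match wins in the
#' priority order EG > LG > TG > EPG > LPG > RG, trying d = +1 before
#' d = -1.
#'
#' @return A `decision_rules` data frame with columns `group`,
#'   `C1`..`C6`, `priority`.
#' @export
default_rules <- function() {
  r <- data.frame(
    group = c("EG", "LG", "TG", "EPG", "LPG", "RG"),
    C1 = c("d", "0", "d", "d", "0", "0"),
    C2 = c("d", "d", "0", "d", "d", "0"),
    C3 = c("0", "0", "0", "d", "d", "d"),
    C4 = c("0", "d", "-d", "0", "d", "0"),
    C5 = c("*", "*", "*", "*", "*", "*"),
    C6 = c("-d", "-d", "*", "0", "0", "*"),
    priority = 1:6,
    stringsAsFactors = FALSE
  )
  class(r) <- c("decision_rules", "data.frame")
  r
}

.validate_rules <- function(rules) {
  cn <- paste0("C", 1:6)
  if (!all(c("group", cn, "priority") %in% names(rules))) {
    stop("rules need columns group, C1..C6, priority", call. = FALSE)
  }
  toks <- unlist(rules[, cn])
  bad <- setdiff(unique(toks), c("d", "-d", "0", "*"))
  if (length(bad)) {
    stop("invalid rule token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (ccol in c("C1", "C2")) {
    if (any(rules[[ccol]] == "*")) {
      stop("every rule must constrain C1 and C2", call. = FALSE)
    }
  }
  rules[order(rules$priority), , drop = FALSE]
}

#' Read / write decision rules
#'
#' Rules files are YAML: one block per group with per-contrast tokens and a
#' priority, e.g. `EG: {C1: d, C2: d, C3: "0", C4: "0", C5: "*", C6: -d,
#' priority: 1}`.
#'
#' @param path file path.
#' @return `read_rules`: a validated `decision_rules` data frame.
#' @export
read_rules <- function(path) {
  y <- yaml::read_yaml(path)
  rows <- lapply(names(y), function(g) {
    b <- y[[g]]
    data.frame(group = g,
               C1 = as.character(b$C1), C2 = as.character(b$C2),
               C3 = as.character(b$C3), C4 = as.character(b$C4),
               C5 = as.character(b$C5), C6 = as.character(b$C6),
               priority = as.integer(b$priority),
               stringsAsFactors = FALSE)
  })
  r <- .validate_rules(do.call(rbind, rows))
  class(r) <- c("decision_rules", "data.frame")
  r
}

#' @rdname read_rules
#' @param rules a `decision_rules` data frame.
#' @export
write_rules <- function(rules, path) {
  rules <- .validate_rules(rules)
  y <- lapply(seq_len(nrow(rules)), function(i) {
    as.list(rules[i, c(paste0("C", 1:6), "priority")])
  })
  names(y) <- rules$group
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Build a significance pattern for one protein
#'
#' @param calls data frame with columns `contrast` (`"C1"`..`"C6"`) and
#'   `call` (in \{-1, 0, +1\}); exactly one row per canonical contrast.
#'   An optional `untestable` column becomes the companion mask.
#' @return Named integer vector of length 6 ordered C1..C6, with attribute
#'   `untestable` (logical mask).
#' @export
build_pattern <- function(calls) {
  ids <- paste0("C", 1:6)
  if (anyDuplicated(calls$contrast)) {
    stop("duplicate contrast entries: ",
         paste(unique(calls$contrast[duplicated(calls$contrast)]),
               collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(ids, calls$contrast)
  if (length(miss)) {
    stop("missing contrast(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(ids, calls$contrast)
  p <- as.integer(calls$call[idx])
  names(p) <- ids
  mask <- if ("untestable" %in% names(calls)) {
    as.logical(calls$untestable[idx])
  } else rep(FALSE, 6)
  attr(p, "untestable") <- mask
  p
}

# does pattern match the rule's token row at direction d?
.rule_matches <- function(pattern, tokens, d) {
  for (i in 1:6) {
    tk <- tokens[[i]]
    if (tk == "*") next
    want <- switch(tk, d = d, `-d` = -d, `0` = 0L)
    if (pattern[[i]] != want) return(FALSE)
  }
  TRUE
}

#' Classify a significance pattern into a kinetic group
#'
#' Evaluates the decision rules for direction +1 first, then -1, in
#' priority order; the first full match wins. Patterns matching no rule are
#' `UNASSIGNED` with direction 0 and go on to profile clustering.
#'
#' @param pattern integer 6-vector over \{-1, 0, +1\} ordered C1..C6
#'   (see [build_pattern()]).
#' @param rules a `decision_rules` table (default [default_rules()]).
#' @return List with `group` (a kinetic group code or `"UNASSIGNED"`) and
#'   `direction` (+1, -1, or 0).
#' @export
classify_pattern <- function(pattern, rules = default_rules()) {
  rules <- .validate_rules(rules)
  cn <- paste0("C", 1:6)
  for (d in c(1L, -1L)) {
    for (i in seq_len(nrow(rules))) {
      if (.rule_matches(pattern, rules[i, cn], d)) {
        return(list(group = rules$group[i], direction = d))
      }
    }
  }
  list(group = "UNASSIGNED", direction = 0L)
}

#' Classify all differentially accumulated proteins
#'
#' Builds the significance pattern of every DAP (protein with at least one
#' nonzero call) and classifies it. Non-DAP proteins are not classified.
#'
#' @param ct a `contrast_table` from [run_contrasts()].
#' @param rules a `decision_rules` table.
#' @return A `kinetic_assignment` data frame (`accession`, `group`,
#'   `direction`), one row per DAP, with attribute `summary`: per-group
#'   counts split by direction.
#' @export
classify_all <- function(ct, rules = default_rules()) {
  rules <- .validate_rules(rules)
  cn <- paste0("C", 1:6)
  ids <- paste0("C", 1:6)
  # wide matrix of calls, proteins x contrasts
  accs <- unique(ct$accession)
  callm <- matrix(0L, nrow = length(accs), ncol = 6,
                  dimnames = list(accs, ids))
  idx <- cbind(match(ct$accession, accs), match(ct$contrast, ids))
  callm[idx] <- as.integer(ct$call)
  dap <- accs[rowSums(callm != 0) > 0]
  out <- data.frame(accession = character(0), group = character(0),
                    direction = integer(0), stringsAsFactors = FALSE)
  if (length(dap)) {
    cls <- lapply(dap, function(a) classify_pattern(callm[a, ], rules))
    out <- data.frame(accession = dap,
                      group = vapply(cls, `[[`, "", "group"),
                      direction = vapply(cls, `[[`, 0L, "direction"),
                      stringsAsFactors = FALSE)
  }
  groups <- c(kinetic_groups(), "UNASSIGNED")
  summ <- expand.grid(group = groups, direction = c(1L, -1L, 0L),
                      stringsAsFactors = FALSE)
  summ$n <- mapply(function(g, d) sum(out$group == g & out$direction == d),
                   summ$group, summ$direction)
  summ <- summ[summ$n > 0 | summ$direction == 1L, ]
  rownames(summ) <- NULL
  structure(out, summary = summ,
            class = c("kinetic_assignment", "data.frame"))
}

#' Write / read kinetic assignments
#' @param assign a `kinetic_assignment` data frame.
#' @param path file path.
#' @export
write_assignments <- function(assign, path) {
  utils::write.table(as.data.frame(assign), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_assignments
#' @export
read_assignments <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(a) <- c("kinetic_assignment", "data.frame")
  a
}

#' Hash of a decision-rule table
#'
#' A short content hash so rule changes are visible in run manifests.
#' @param rules a `decision_rules` table.
#' @return Character scalar.
#' @export
rules_hash <- function(rules = default_rules()) {
  rules <- .validate_rules(rules)
  s <- paste(apply(rules, 1, paste, collapse = "|"), collapse = ";")
  # small polynomial rolling hash, enough to spot edits
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
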