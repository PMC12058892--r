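#' Observed FCPC data sets
#'
#' A data set is the pair `(patterns, freqs)`: the distinct observed
#' response patterns (each an asymmetric complete relation, stored as bit
#' rows) with their nonnegative observed frequencies summing to the sample
#' size `N`.
#'
#' @param universe a [pair_universe()] or [two_component_design()].
#' @param patterns 0/1 matrix, one row per distinct pattern, or a list of
#'   [relation()]s.
#' @param freqs nonnegative frequencies, one per pattern, with positive sum.
#' @return An object of class `korders_dataset` with fields `universe`,
#'   `bits`, `freqs`.
#' @export
korders_dataset <- function(universe, patterns, freqs) {
  universe <- as_universe(universe)
  if (is.list(patterns))
    patterns <- do.call(rbind, lapply(patterns, function(r) {
      stopifnot(inherits(r, "relation"))
      check_same_universe(r$universe, universe)
      r$bits
    }))
  bits <- as.matrix(patterns)
  storage.mode(bits) <- "integer"
  if (ncol(bits) != universe$m || !all(bits %in% c(0L, 1L)))
    stop("pattern bits must be 0/1 with one column per canonical pair")
  if (anyDuplicated(bits_key(bits))) stop("patterns must be distinct")
  freqs <- as.numeric(freqs)
  if (length(freqs) != nrow(bits) || any(freqs < 0) || sum(freqs) <= 0)
    stop("'freqs' must be nonnegative, one per pattern, with positive total")
  dimnames(bits) <- NULL
  structure(list(universe = universe, bits = bits, freqs = freqs),
            class = "korders_dataset")
}

#' @export
print.korders_dataset <- function(x, ...) {
  cat("FCPC dataset: N =", format(sum(x$freqs)), "responses,",
      nrow(x$bits), "distinct patterns,", x$universe$m, "stimuli\n")
  invisible(x)
}

#' Total sample size of a data set
#' @param data a [korders_dataset()].
#' @return `sum(freqs)`.
#' @export
dataset_n <- function(data) {
  stopifnot(inherits(data, "korders_dataset"))
  sum(data$freqs)
}

#' Aggregate respondent-level responses into a data set
#'
#' @param universe a [pair_universe()] or [two_component_design()].
#' @param responses 0/1 matrix, one row per respondent (duplicates allowed;
#'   they aggregate into the pattern frequencies).
#' @return A [korders_dataset()].
#' @export
dataset_from_responses <- function(universe, responses) {
  universe <- as_universe(universe)
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  if (ncol(responses) != universe$m || !all(responses %in% c(0L, 1L)))
    stop("'responses' must be 0/1 with one column per canonical pair")
  key <- bits_key(responses)
  tab <- table(key)
  first <- match(names(tab), key)
  korders_dataset(universe, responses[first, , drop = FALSE], as.numeric(tab))
}

#' Read an FCPC data set from CSV/TSV
#'
#' Expected layout: one row per respondent, one column per unordered
#' stimulus named `"a|b"` (any pair orientation and column order accepted;
#' the universe and its canonical order are inferred from the headers), each
#' cell 1 if the first-named option was chosen and 0 otherwise. Rows with
#' any missing or non-binary cell are rejected (the clustering requires
#' complete cases); their count is reported in a warning and attached as
#' attribute `n_rejected`.
#'
#' @param path CSV (comma) or TSV (tab, for extensions `.tsv`/`.txt`) file.
#' @return A [korders_dataset()], with attribute `n_rejected`.
#' @export
read_dataset <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  labels <- colnames(df)
  parts <- strsplit(labels, "|", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("malformed header: every column must be named 'option|option'")
  opts_seen <- unique(unlist(parts))
  universe <- pair_universe(opts_seen)
  a <- option_index(universe, vapply(parts, `[`, "", 1L))
  b <- option_index(universe, vapply(parts, `[`, "", 2L))
  if (any(a == b)) stop("malformed header: a stimulus must pair two distinct options")
  j <- universe$pair_id[cbind(a, b)]
  if (anyDuplicated(j) || length(j) != universe$m)
    stop("inconsistent pair set: headers must cover every unordered pair exactly once")
  raw <- suppressWarnings(matrix(as.numeric(as.matrix(df)), nrow = nrow(df)))
  bad_cell <- is.na(raw) | !(raw %in% c(0, 1))
  keep <- rowSums(bad_cell) == 0L
  n_rejected <- sum(!keep)
  if (n_rejected > 0L)
    warning(sprintf("%d row(s) with missing or non-binary cells rejected", n_rejected))
  if (!any(keep)) stop("no complete rows in the file")
  raw <- raw[keep, , drop = FALSE]
  bits <- matrix(0L, nrow(raw), universe$m)
  # cell = 1 means the first-named option chosen; canonicalize orientation
  for (c_ in seq_along(j)) {
    v <- as.integer(raw[, c_])
    bits[, j[c_]] <- if (a[c_] < b[c_]) 1L - v else v
  }
  out <- dataset_from_responses(universe, bits)
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write an FCPC data set to CSV
#'
#' Emits one row per respondent (pattern frequencies must be integral) in
#' the canonical column order, so that [read_dataset()] round-trips the
#' data set exactly.
#'
#' @param data a [korders_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "korders_dataset"))
  if (any(abs(data$freqs - round(data$freqs)) > 1e-9))
    stop("respondent-level output requires integral frequencies")
  rows <- rep(seq_len(nrow(data$bits)), times = round(data$freqs))
  resp <- 1L - data$bits[rows, , drop = FALSE]  # 1 = first-named (reference) option chosen
  colnames(resp) <- data$universe$pair_labels
  utils::write.csv(as.data.frame(resp), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
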