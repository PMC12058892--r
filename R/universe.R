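#' Universe of options and their canonical unordered pairs
#'
#' A pair universe fixes the option set of a forced-choice paired-comparison
#' (FCPC) experiment together with a canonical ordering of its
#' `choose(n, 2)` unordered pairs (lexicographic by option index) and an
#' orientation convention: for the pair `{a, b}` with `index(a) < index(b)`,
#' the *reference* ordered pair is `(a, b)`. Every preference relation over
#' the universe is encoded against this fixed pair order (see [relation()]).
#'
#' @param options character vector of distinct option identifiers (length
#'   at least 2). The order given here is the canonical option order.
#'
#' @return An object of class `pair_universe` with components `options`,
#'   `n` (number of options), `m` (number of unordered pairs), `pair_i` /
#'   `pair_j` (option indices of each canonical pair, `pair_i < pair_j`),
#'   `pair_labels` (`"a|b"` per pair) and `pair_id` (n-by-n lookup matrix
#'   from an option index pair to the canonical pair index).
#'
#' @examples
#' u <- pair_universe(c("a", "b", "c"))
#' u$pair_labels
#' @export
pair_universe <- function(options) {
  options <- as.character(options)
  if (anyDuplicated(options)) stop("option identifiers must be distinct")
  if (length(options) < 2L) stop("a pair universe needs at least two options")
  if (any(grepl("|", options, fixed = TRUE)))
    stop("option identifiers must not contain '|'")
  n <- length(options)
  pair_i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  pair_j <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n), use.names = FALSE)
  m <- length(pair_i)
  pair_id <- matrix(0L, n, n)
  pair_id[cbind(pair_i, pair_j)] <- seq_len(m)
  pair_id[cbind(pair_j, pair_i)] <- seq_len(m)
  structure(
    list(options = options, n = n, m = m,
         pair_i = pair_i, pair_j = pair_j,
         pair_labels = paste0(options[pair_i], "|", options[pair_j]),
         pair_id = pair_id),
    class = "pair_universe")
}

#' @export
print.pair_universe <- function(x, ...) {
  cat("Pair universe:", x$n, "options,", x$m, "unordered pairs\n")
  cat("  options:", paste(utils::head(x$options, 8L), collapse = ", "),
      if (x$n > 8L) "..." else "", "\n")
  invisible(x)
}

same_universe <- function(u1, u2) {
  identical(u1$options, u2$options)
}

check_same_universe <- function(u1, u2) {
  if (!same_universe(u1, u2)) stop("objects are defined over different universes")
  invisible(TRUE)
}

option_index <- function(universe, option) {
  i <- match(as.character(option), universe$options)
  if (anyNA(i)) stop("unknown option(s): ",
                     paste(option[is.na(i)], collapse = ", "))
  i
}

#' Two-component option design with its pointwise order
#'
#' In a two-component FCPC design every option is a pair `(v, w)` of levels
#' of two linearly ordered components (e.g. economy and health severity).
#' Level 1 is the *least severe* level, and an option is preferred to
#' another whenever it is componentwise at most as severe and not identical
#' (the "preferred = less severe" convention). The set of all such dominance
#' pairs is the pointwise (coordinate-wise) order `P0`, a strict partial
#' order; the monotonicity axiom for a complete preference relation amounts
#' to containing `P0` (see [satisfies_ma()]).
#'
#' Options are labelled `"v:w"` and canonically ordered lexicographically by
#' `(v, w)`.
#'
#' @param v_levels,w_levels number of levels of the first and second
#'   component (at least 2 each).
#' @param components length-2 character vector naming the two components;
#'   used by [health_economy_aggregates()], which needs to know which
#'   component is `"health"`.
#'
#' @return An object of class `two_component_design` with the option
#'   `universe` (a [pair_universe()]), the level matrix `comp`
#'   (n-by-2), and `p0_dir`: for each canonical pair, `0` if the reference
#'   orientation is the dominance (P0) orientation, `1` if the reversed one
#'   is, and `NA` for non-monotone (incomparable) stimuli.
#'
#' @examples
#' d <- two_component_design(4, 4)
#' sum(!is.na(d$p0_dir))  # monotone stimuli: 84 of 120
#' @export
two_component_design <- function(v_levels, w_levels,
                                 components = c("economy", "health")) {
  v_levels <- as.integer(v_levels); w_levels <- as.integer(w_levels)
  if (v_levels < 2L || w_levels < 2L) stop("each component needs at least 2 levels")
  components <- as.character(components)
  if (length(components) != 2L || anyDuplicated(components))
    stop("'components' must be two distinct names")
  comp <- cbind(v = rep(seq_len(v_levels), each = w_levels),
                w = rep(seq_len(w_levels), times = v_levels))
  universe <- pair_universe(paste0(comp[, 1L], ":", comp[, 2L]))
  i <- universe$pair_i; j <- universe$pair_j
  i_dom_j <- comp[i, 1L] <= comp[j, 1L] & comp[i, 2L] <= comp[j, 2L]
  j_dom_i <- comp[j, 1L] <= comp[i, 1L] & comp[j, 2L] <= comp[i, 2L]
  p0_dir <- rep(NA_integer_, universe$m)
  p0_dir[i_dom_j] <- 0L
  p0_dir[j_dom_i] <- 1L   # cannot occur under lexicographic option order, kept for safety
  structure(
    list(v_levels = v_levels, w_levels = w_levels, components = components,
         universe = universe, comp = comp, p0_dir = p0_dir),
    class = "two_component_design")
}

#' @export
print.two_component_design <- function(x, ...) {
  cat("Two-component design:", x$v_levels, "x", x$w_levels, "levels (",
      paste(x$components, collapse = " x "), ")\n")
  cat("  ", x$universe$n, "options,", x$universe$m, "stimuli (",
      sum(!is.na(x$p0_dir)), "monotone,", sum(is.na(x$p0_dir)), "non-monotone )\n")
  invisible(x)
}

#' Pointwise order of a two-component design
#'
#' Returns the pointwise (coordinate-wise) order `P0` of the design as a set
#' of ordered option pairs: `(o1, o2)` belongs to `P0` when `o1` is
#' componentwise at most as severe as `o2` and the two options differ.
#'
#' @param design a [two_component_design()].
#' @return A two-column character matrix of ordered pairs
#'   (columns `preferred`, `over`).
#' @export
pointwise_order <- function(design) {
  stopifnot(inherits(design, "two_component_design"))
  u <- design$universe
  keep <- !is.na(design$p0_dir)
  dir <- design$p0_dir[keep]
  a <- ifelse(dir == 0L, u$pair_i[keep], u$pair_j[keep])
  b <- ifelse(dir == 0L, u$pair_j[keep], u$pair_i[keep])
  cbind(preferred = u$options[a], over = u$options[b])
}

#' Is a stimulus monotone under a two-component design?
#'
#' A stimulus (unordered pair of options) is *monotone* when one option
#' weakly dominates the other in both components, i.e. the two options do
#' not strictly conflict across the components; choosing the dominated
#' option then violates the monotonicity axiom.
#'
#' @param design a [two_component_design()].
#' @param stimulus character vector of two distinct option labels.
#' @return `TRUE` or `FALSE`.
#' @examples
#' d <- two_component_design(4, 4)
#' is_monotone_stimulus(d, c("1:2", "1:3"))  # TRUE: tied first component
#' is_monotone_stimulus(d, c("1:2", "2:1"))  # FALSE: strict conflict
#' @export
is_monotone_stimulus <- function(design, stimulus) {
  stopifnot(inherits(design, "two_component_design"))
  idx <- option_index(design$universe, stimulus)
  if (length(idx) != 2L || idx[1L] == idx[2L]) stop("stimulus options must be two distinct options")
  !is.na(design$p0_dir[design$universe$pair_id[idx[1L], idx[2L]]])
}
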