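#' Preference relations as oriented pair vectors
#'
#' An asymmetric, complete binary relation on the option set ("preference
#' relation", or response pattern of one respondent) contains exactly one
#' orientation of each unordered pair. It is stored as a 0/1 vector over the
#' universe's canonical pairs: bit 0 means the relation contains the
#' reference ordered pair (lower-index option preferred), bit 1 the reversed
#' one. The encoding is asymmetric and complete by construction and
#' round-trips losslessly with the set-of-ordered-pairs form
#' ([relation_pairs()], [relation_from_pairs()]).
#'
#' @param universe a [pair_universe()] (or a [two_component_design()], whose
#'   universe is used).
#' @param bits integer/numeric vector of 0s and 1s, one per canonical pair.
#'
#' @return An object of class `relation` with fields `universe` and `bits`.
#' @examples
#' u <- pair_universe(c("a", "b", "c"))
#' r <- relation(u, c(0, 0, 0))   # a > b > c
#' relation_pairs(r)
#' @export
relation <- function(universe, bits) {
  universe <- as_universe(universe)
  bits <- as.integer(bits)
  if (length(bits) != universe$m || !all(bits %in% c(0L, 1L)))
    stop("'bits' must be a 0/1 vector with one entry per canonical pair")
  structure(list(universe = universe, bits = bits), class = "relation")
}

as_universe <- function(x) {
  if (inherits(x, "two_component_design")) return(x$universe)
  if (inherits(x, "pair_universe")) return(x)
  stop("expected a 'pair_universe' or 'two_component_design'")
}

#' @export
print.relation <- function(x, ...) {
  p <- relation_pairs(x)
  cat("Preference relation on {", paste(x$universe$options, collapse = ", "),
      "}:\n  {", paste(sprintf("(%s,%s)", p[, 1L], p[, 2L]), collapse = ", "),
      "}\n", sep = "")
  invisible(x)
}

#' @export
format.relation <- function(x, ...) paste(x$bits, collapse = "")

#' Ordered-pair (set) representation of a relation
#'
#' Inverse of [relation_from_pairs()]: returns, for each canonical unordered
#' pair, the ordered pair the relation contains.
#'
#' @param rel a [relation()].
#' @return Two-column character matrix (`preferred`, `over`), one row per
#'   canonical pair, in canonical pair order.
#' @export
relation_pairs <- function(rel) {
  stopifnot(inherits(rel, "relation"))
  u <- rel$universe
  a <- ifelse(rel$bits == 0L, u$pair_i, u$pair_j)
  b <- ifelse(rel$bits == 0L, u$pair_j, u$pair_i)
  cbind(preferred = u$options[a], over = u$options[b])
}

#' Build a relation from a set of ordered pairs
#'
#' @param universe a [pair_universe()] or [two_component_design()].
#' @param pairs two-column matrix or data frame of ordered option pairs
#'   (`preferred`, `over`); exactly one orientation of every unordered pair
#'   of the universe must be present.
#' @return A [relation()].
#' @examples
#' u <- pair_universe(c("a", "b", "c"))
#' relation_from_pairs(u, rbind(c("a","b"), c("b","c"), c("a","c")))
#' @export
relation_from_pairs <- function(universe, pairs) {
  universe <- as_universe(universe)
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("'pairs' must have two columns")
  a <- option_index(universe, pairs[, 1L])
  b <- option_index(universe, pairs[, 2L])
  if (any(a == b)) stop("ordered pairs must involve two distinct options")
  j <- universe$pair_id[cbind(a, b)]
  if (anyDuplicated(j)) stop("both orientations (or duplicates) of a pair supplied")
  if (length(j) != universe$m) stop("every unordered pair must appear exactly once")
  bits <- integer(universe$m)
  bits[j] <- as.integer(a > b)
  relation(universe, bits)
}

#' Map a permutation of the options to its strict linear order
#'
#' The permutation lists the options from most to least preferred; e.g. on
#' four options the permutation `c(1, 3, 2, 4)` yields the order
#' `s1 > s3 > s2 > s4`.
#'
#' @param universe a [pair_universe()] or [two_component_design()].
#' @param perm permutation of all option indices (integer) or labels
#'   (character), most preferred first.
#' @return A [relation()] that is a strict linear order.
#' @export
perm_to_order <- function(universe, perm) {
  universe <- as_universe(universe)
  if (is.character(perm)) perm <- option_index(universe, perm)
  perm <- as.integer(perm)
  if (length(perm) != universe$n || !setequal(perm, seq_len(universe$n)))
    stop("'perm' must be a permutation of all option indices")
  pos <- integer(universe$n)
  pos[perm] <- seq_len(universe$n)
  relation(universe, as.integer(pos[universe$pair_i] > pos[universe$pair_j]))
}

relation_adjacency <- function(rel) {
  u <- rel$universe
  A <- matrix(FALSE, u$n, u$n)
  a <- ifelse(rel$bits == 0L, u$pair_i, u$pair_j)
  b <- ifelse(rel$bits == 0L, u$pair_j, u$pair_i)
  A[cbind(a, b)] <- TRUE
  A
}

bits_transitive <- function(bits, universe) {
  A <- matrix(FALSE, universe$n, universe$n)
  a <- ifelse(bits == 0L, universe$pair_i, universe$pair_j)
  b <- ifelse(bits == 0L, universe$pair_j, universe$pair_i)
  A[cbind(a, b)] <- TRUE
  # complete + asymmetric: a violation a->b->c with c->a shows up as (A^2 & t(A))
  !any((A %*% A > 0) & t(A))
}

#' Is a relation transitive?
#'
#' For asymmetric complete relations, transitivity makes the relation a
#' strict linear order (a full ranking).
#'
#' @param rel a [relation()].
#' @return `TRUE` or `FALSE`.
#' @export
is_transitive <- function(rel) {
  stopifnot(inherits(rel, "relation"))
  bits_transitive(rel$bits, rel$universe)
}

#' Is a set of ordered pairs acyclic?
#'
#' Checks an arbitrary (not necessarily complete) set of ordered option
#' pairs for directed cycles, by repeated elimination of sources
#' (topological sort).
#'
#' @param pairs two-column matrix/data frame of ordered option pairs; may be
#'   empty.
#' @param universe a [pair_universe()] or [two_component_design()].
#' @return `TRUE` if no directed cycle exists.
#' @export
is_acyclic <- function(pairs, universe) {
  universe <- as_universe(universe)
  pairs <- as.matrix(pairs)
  if (length(pairs) == 0L || nrow(pairs) == 0L) return(TRUE)
  a <- option_index(universe, pairs[, 1L])
  b <- option_index(universe, pairs[, 2L])
  if (any(a == b)) return(FALSE)  # a loop is a cycle of length 1
  n <- universe$n
  A <- matrix(FALSE, n, n)
  A[cbind(a, b)] <- TRUE
  active <- rep(TRUE, n)
  repeat {
    if (!any(active)) return(TRUE)
    indeg <- colSums(A[active, , drop = FALSE])
    src <- active & indeg == 0
    if (!any(src)) return(FALSE)
    active[src] <- FALSE
    A[src, ] <- FALSE
  }
}

#' Canonical (symmetric-difference) distance between two relations
#'
#' The size of the symmetric difference of the two pair sets; equals twice
#' the Hamming distance between the bit encodings, hence always even, with
#' range 0 to `2 * m` over `m` unordered pairs. Distance 2 means the two
#' relations differ by a single inverted pair ("neighbors" when both are
#' linear orders).
#'
#' @param r1,r2 [relation()]s over the same universe.
#' @return A nonnegative even integer.
#' @export
symdiff_distance <- function(r1, r2) {
  stopifnot(inherits(r1, "relation"), inherits(r2, "relation"))
  check_same_universe(r1$universe, r2$universe)
  2L * sum(r1$bits != r2$bits)
}

#' Invert one ordered pair of a relation
#'
#' Returns `R - (a,b) = (R \ {(a,b)}) u {(b,a)}`; the pair must belong to
#' the relation. Flipping twice (the pair, then its inverse) restores the
#' original relation.
#'
#' @param rel a [relation()].
#' @param pair character vector `c(a, b)` with `(a, b)` in the relation.
#' @return A [relation()].
#' @export
flip <- function(rel, pair) {
  stopifnot(inherits(rel, "relation"))
  u <- rel$universe
  idx <- option_index(u, pair)
  if (length(idx) != 2L || idx[1L] == idx[2L]) stop("'pair' must name two distinct options")
  j <- u$pair_id[idx[1L], idx[2L]]
  in_rel <- if (idx[1L] < idx[2L]) rel$bits[j] == 0L else rel$bits[j] == 1L
  if (!in_rel) stop(sprintf("pair (%s,%s) is not in the relation", pair[1L], pair[2L]))
  bits <- rel$bits
  bits[j] <- 1L - bits[j]
  relation(u, bits)
}

#' Does a relation satisfy the monotonicity axiom?
#'
#' For an asymmetric complete relation over a product of two totally
#' ordered components, the monotonicity axiom (orderings of one component's
#' levels transfer across all levels of the other) is equivalent to
#' containing the design's pointwise order `P0`: every monotone stimulus
#' must be resolved in favor of the dominating (componentwise less severe)
#' option.
#'
#' @param rel a [relation()] over the design's universe.
#' @param design a [two_component_design()].
#' @return `TRUE` or `FALSE`.
#' @export
satisfies_ma <- function(rel, design) {
  stopifnot(inherits(rel, "relation"), inherits(design, "two_component_design"))
  check_same_universe(rel$universe, design$universe)
  cmp <- !is.na(design$p0_dir)
  all(rel$bits[cmp] == design$p0_dir[cmp])
}

#' Enumerate all preference relations on a universe
#'
#' All `2^m` asymmetric complete relations, as a bit matrix (one row per
#' relation). Intended for small universes (guarded at `m <= 21`).
#'
#' @param universe a [pair_universe()] or [two_component_design()].
#' @return Integer 0/1 matrix with `2^m` rows and `m` columns.
#' @export
all_relations <- function(universe) {
  universe <- as_universe(universe)
  m <- universe$m
  if (m > 21L) stop("universe too large to enumerate all relations")
  bits <- as.matrix(expand.grid(rep(list(0:1), m), KEEP.OUT.ATTRS = FALSE))
  dimnames(bits) <- NULL
  storage.mode(bits) <- "integer"
  bits
}

#' Enumerate all strict linear orders on a universe
#'
#' One row of bits per permutation of the options (`n!` orders; guarded at
#' `n <= 8`).
#'
#' @param universe a [pair_universe()] or [two_component_design()].
#' @return Integer 0/1 matrix with `n!` rows and `m` columns.
#' @export
all_linear_orders <- function(universe) {
  universe <- as_universe(universe)
  n <- universe$n
  if (n > 8L) stop("universe too large to enumerate all linear orders")
  perms <- permutations_of(n)
  out <- matrix(0L, nrow(perms), universe$m)
  for (r in seq_len(nrow(perms))) {
    pos <- integer(n); pos[perms[r, ]] <- seq_len(n)
    out[r, ] <- as.integer(pos[universe$pair_i] > pos[universe$pair_j])
  }
  out
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}
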