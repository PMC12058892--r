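#' Admissible classes of strict linear orders
#'
#' The transitive centroid adjustments operate inside a pre-specified class
#' of strict linear orders: either all of them (`"linear_orders"`), or only
#' those that additionally satisfy the monotonicity axiom of a two-component
#' design (`"linear_orders_ma"`, i.e. orders containing the pointwise order
#' `P0`).
#'
#' @param kind `"linear_orders"` or `"linear_orders_ma"`.
#' @param design a [two_component_design()]; required for
#'   `"linear_orders_ma"`.
#' @return An object of class `constraint_set`.
#' @export
constraint_set <- function(kind = c("linear_orders", "linear_orders_ma"),
                           design = NULL) {
  kind <- match.arg(kind)
  if (kind == "linear_orders_ma") {
    if (!inherits(design, "two_component_design"))
      stop("'linear_orders_ma' requires a two_component_design")
  } else if (!is.null(design) && !inherits(design, "two_component_design")) {
    stop("'design' must be a two_component_design or NULL")
  }
  structure(list(kind = kind, design = design), class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat("Constraint set:",
      if (x$kind == "linear_orders") "all strict linear orders"
      else sprintf("strict linear orders satisfying MA (%d x %d design)",
                   x$design$v_levels, x$design$w_levels), "\n")
  invisible(x)
}

#' Membership of a relation in a constraint set
#'
#' @param rel a [relation()].
#' @param constraints a [constraint_set()].
#' @return `TRUE` if `rel` is a strict linear order of the admissible class.
#' @export
in_constraints <- function(rel, constraints) {
  stopifnot(inherits(rel, "relation"), inherits(constraints, "constraint_set"))
  if (!is_transitive(rel)) return(FALSE)
  if (constraints$kind == "linear_orders_ma" &&
      !satisfies_ma(rel, constraints$design)) return(FALSE)
  TRUE
}

#' Neighborhood of a linear order within a constraint set
#'
#' All admissible orders at canonical distance exactly 2 from `rel`
#' (i.e. obtainable by inverting a single pair).
#'
#' @param rel a [relation()] belonging to `constraints`.
#' @param constraints a [constraint_set()].
#' @return A list of [relation()]s (possibly empty).
#' @export
neighbors <- function(rel, constraints) {
  stopifnot(inherits(rel, "relation"))
  if (!in_constraints(rel, constraints)) stop("'rel' is not in the constraint set")
  out <- list()
  for (j in seq_len(rel$universe$m)) {
    bits <- rel$bits
    bits[j] <- 1L - bits[j]
    cand <- relation(rel$universe, bits)
    if (in_constraints(cand, constraints)) out[[length(out) + 1L]] <- cand
  }
  out
}

#' Free pairs of a linear order
#'
#' The ordered pairs `(a, b)` of `rel` whose inversion keeps the relation
#' inside the constraint set; only these may be flipped by the path-finding
#' transitive centroid adjustment. Computed by the generic membership test
#' (flip, then check transitivity and, if applicable, the monotonicity
#' axiom). For plain linear orders the free pairs are exactly the adjacent
#' pairs of the ranking, hence there are `n - 1` of them.
#'
#' @param rel a [relation()] belonging to `constraints`.
#' @param constraints a [constraint_set()].
#' @return Two-column character matrix of ordered pairs (possibly 0 rows).
#' @export
free_pairs <- function(rel, constraints) {
  stopifnot(inherits(rel, "relation"))
  if (!in_constraints(rel, constraints)) stop("'rel' is not in the constraint set")
  u <- rel$universe
  keep <- logical(u$m)
  for (j in seq_len(u$m)) {
    bits <- rel$bits
    bits[j] <- 1L - bits[j]
    keep[j] <- in_constraints(relation(u, bits), constraints)
  }
  a <- ifelse(rel$bits == 0L, u$pair_i, u$pair_j)[keep]
  b <- ifelse(rel$bits == 0L, u$pair_j, u$pair_i)[keep]
  cbind(preferred = u$options[a], over = u$options[b])
}
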