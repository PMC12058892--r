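# Internal engine ------------------------------------------------------------
# Patterns, centroids and states are handled as 0/1 matrices (rows = relations,
# columns = canonical pairs). The canonical distance |X delta C| equals twice
# the Hamming distance between bit rows.

hamming_matrix <- function(X, C) {
  # X: P x m, C: k x m -> P x k matrix of Hamming distances
  X <- as.matrix(X); C <- as.matrix(C)
  X %*% t(1 - C) + (1 - X) %*% t(C)
}

min_discrepancy_partition <- function(X, F_, C) {
  H <- hamming_matrix(X, C)
  hmin <- do.call(pmin, as.data.frame(H))
  member <- (H - hmin) < 0.5          # integer-valued; exact minimum
  f <- member * (F_ / rowSums(member))
  list(f = f, D = H, dmin = 2 * hmin)
}

# weighted proportion, per canonical pair, of patterns containing the
# reference orientation (bit 0), given normalized cluster weights w
marginal_ref <- function(X, w) {
  drop(crossprod(1 - X, w))
}

force_ma <- function(p_ref, p0_dir) {
  if (is.null(p0_dir)) return(p_ref)
  p_ref[!is.na(p0_dir) & p0_dir == 0L] <- 1
  p_ref[!is.na(p0_dir) & p0_dir == 1L] <- 0
  p_ref
}

# average half distance of a relation (bits) from a cluster summarized by its
# reference-orientation marginals: sum over pairs of p(orientation not in L)
half_distance_from_marginals <- function(bits, p_ref) {
  sum(ifelse(bits == 0L, 1 - p_ref, p_ref))
}

kmodes_bits <- function(p_ref) {
  bits <- ifelse(p_ref > 0.5, 0L, 1L)
  ties <- which(abs(p_ref - 0.5) < 1e-12)
  if (length(ties)) bits[ties] <- as.integer(stats::runif(length(ties)) < 0.5)
  bits
}

bits_to_ranking <- function(bits, universe) {
  wins <- tabulate(c(universe$pair_i[bits == 0L], universe$pair_j[bits == 1L]),
                   nbins = universe$n)
  order(-wins)
}

ranking_to_bits <- function(ranking, universe) {
  pos <- integer(universe$n)
  pos[ranking] <- seq_len(universe$n)
  as.integer(pos[universe$pair_i] > pos[universe$pair_j])
}

# Path-finding transitive centroid adjustment on raw bits. Relies on the
# adjacent-transposition characterization of free pairs: for a strict linear
# order the free pairs are exactly the adjacent pairs of its ranking (under MA,
# those not in P0 -- excluded automatically since their forced marginal is 1).
tca_bits <- function(start_bits, p_ref, universe, p0_dir = NULL) {
  p_ref <- force_ma(p_ref, p0_dir)
  ranking <- bits_to_ranking(start_bits, universe)
  n <- universe$n
  for (step in seq_len(100000L)) {
    u <- ranking[-n]; v <- ranking[-1L]
    j <- universe$pair_id[cbind(pmin(u, v), pmax(u, v))]
    p_cur <- ifelse(u < v, p_ref[j], 1 - p_ref[j])
    cand <- which(p_cur < 0.5 - 1e-12)
    if (!length(cand)) return(ranking_to_bits(ranking, universe))
    best <- cand[p_cur[cand] < min(p_cur[cand]) + 1e-12]
    sel <- best[which.min(j[best])]   # deterministic tie-break: lowest pair index
    ranking[c(sel, sel + 1L)] <- ranking[c(sel + 1L, sel)]
  }
  stop("transitive centroid adjustment failed to terminate")  # unreachable
}

# Greedy transitive centroid adjustment: insert orientations in decreasing
# order of marginal proportion, keeping the relation acyclic (reachability is
# maintained incrementally). start_adj, when given, is pre-inserted (must be
# acyclic); under MA the forced marginals make the P0 orientations enter first,
# which is equivalent to starting from P0.
greedy_bits <- function(p_ref, universe, p0_dir = NULL, start_adj = NULL) {
  p_ref <- force_ma(p_ref, p0_dir)
  n <- universe$n; m <- universe$m
  if (is.null(start_adj) && !is.null(p0_dir)) {
    # start from the pointwise order: its pairs are carried to the output
    # unconditionally, not just favored by their forced marginal of 1
    start_adj <- matrix(FALSE, n, n)
    cmp <- !is.na(p0_dir)
    a0 <- ifelse(p0_dir[cmp] == 0L, universe$pair_i[cmp], universe$pair_j[cmp])
    b0 <- ifelse(p0_dir[cmp] == 0L, universe$pair_j[cmp], universe$pair_i[cmp])
    start_adj[cbind(a0, b0)] <- TRUE
  }
  a <- c(universe$pair_i, universe$pair_j)
  b <- c(universe$pair_j, universe$pair_i)
  p <- c(p_ref, 1 - p_ref)
  h <- c(2L * seq_len(m) - 1L, 2L * seq_len(m))  # injective; reference first on ties
  ord <- order(-p, h)
  A <- matrix(FALSE, n, n)
  Rch <- diag(n) > 0
  if (!is.null(start_adj)) {
    edges <- which(start_adj, arr.ind = TRUE)
    for (r in seq_len(nrow(edges))) {
      i1 <- edges[r, 1L]; j1 <- edges[r, 2L]
      if (Rch[j1, i1]) stop("'start' relation is cyclic")
      A[i1, j1] <- TRUE
      Rch[Rch[, i1], Rch[j1, ]] <- TRUE
    }
  }
  for (t in ord) {
    at <- a[t]; bt <- b[t]
    if (A[at, bt] || A[bt, at] || Rch[bt, at]) next
    A[at, bt] <- TRUE
    Rch[Rch[, at], Rch[bt, ]] <- TRUE
  }
  as.integer(!A[cbind(universe$pair_i, universe$pair_j)])
}

# Public cluster interface ----------------------------------------------------

#' Weighted clusters of response patterns
#'
#' A cluster is a pair `(G, p)`: a set of response patterns with
#' nonnegative weights summing to 1 (weights may be fractional because
#' patterns tied between several centroids split their frequency equally).
#'
#' @param universe a [pair_universe()] or [two_component_design()].
#' @param patterns 0/1 bit matrix (one row per pattern) or list of
#'   [relation()]s.
#' @param weights nonnegative weights, one per pattern, summing to 1 within
#'   `1e-9`.
#' @return An object of class `korders_cluster`.
#' @export
korders_cluster <- function(universe, patterns, weights) {
  universe <- as_universe(universe)
  if (is.list(patterns))
    patterns <- do.call(rbind, lapply(patterns, function(r) r$bits))
  bits <- as.matrix(patterns)
  storage.mode(bits) <- "integer"
  weights <- as.numeric(weights)
  if (length(weights) != nrow(bits) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    stop("'weights' must be nonnegative and sum to 1")
  dimnames(bits) <- NULL
  structure(list(universe = universe, bits = bits, weights = weights),
            class = "korders_cluster")
}

#' @export
print.korders_cluster <- function(x, ...) {
  cat("Cluster: ", nrow(x$bits), " weighted patterns on ",
      x$universe$n, " options\n", sep = "")
  invisible(x)
}

#' Minimum-discrepancy classification of patterns to centroids
#'
#' Assigns each observed pattern's frequency to the centroid(s) at minimum
#' canonical distance, split equally on ties: `f(X, C) = F(X) / |C_X|` for
#' `C` among the closest centroids and 0 otherwise. The result satisfies
#' the partition-function conditions `f >= 0` and
#' `sum_C f(X, C) = F(X)`, and minimizes the overall discrepancy for the
#' given centroid set.
#'
#' @param data a [korders_dataset()].
#' @param centroids a [preference_structure()] (centroids need not be
#'   transitive).
#' @return Numeric matrix `f` (patterns by centroids) of class
#'   `partition_function`.
#' @export
classify <- function(data, centroids) {
  stopifnot(inherits(data, "korders_dataset"),
            inherits(centroids, "preference_structure"))
  check_same_universe(data$universe, centroids$universe)
  if (nrow(centroids$bits) == 0L) stop("centroid set must be nonempty")
  f <- min_discrepancy_partition(data$bits, data$freqs, centroids$bits)$f
  class(f) <- c("partition_function", class(f))
  f
}

#' Overall discrepancy of a clustering
#'
#' The weighted sum of canonical distances
#' `sum_C sum_X f(X, C) |X delta C|`; with a minimum-discrepancy partition
#' this equals `sum_X F(X) d_min(X, C)`, the quantity the k-modes /
#' k-orders iterations drive down.
#'
#' @param data a [korders_dataset()].
#' @param centroids a [preference_structure()].
#' @param partition optional partition function from [classify()]; when
#'   omitted, the minimum-discrepancy partition is used.
#' @return Nonnegative number.
#' @export
overall_discrepancy <- function(data, centroids, partition = NULL) {
  stopifnot(inherits(data, "korders_dataset"),
            inherits(centroids, "preference_structure"))
  check_same_universe(data$universe, centroids$universe)
  H <- hamming_matrix(data$bits, centroids$bits)
  if (is.null(partition)) {
    hmin <- do.call(pmin, as.data.frame(H))
    return(sum(data$freqs * 2 * hmin))
  }
  partition <- unclass(partition)
  if (!all(dim(partition) == dim(H))) stop("partition has inconsistent shape")
  sum(partition * 2 * H)
}

#' Extract the cluster represented by one centroid
#'
#' Normalizes one column of a partition function into a cluster `(G, p)`
#' (patterns with positive assigned mass and their relative weights).
#'
#' @param data a [korders_dataset()].
#' @param partition partition function from [classify()].
#' @param which column (centroid) index.
#' @return A [korders_cluster()], or `NULL` for an empty cluster.
#' @export
cluster_of <- function(data, partition, which) {
  stopifnot(inherits(data, "korders_dataset"))
  fc <- unclass(partition)[, which]
  s <- sum(fc)
  if (s <= 0) return(NULL)
  keep <- fc > 0
  korders_cluster(data$universe, data$bits[keep, , drop = FALSE], fc[keep] / s)
}

#' Marginal proportions of the ordered pairs in a cluster
#'
#' For every ordered pair `(a, b)`, the weighted share `p(a, b)` of cluster
#' patterns containing `(a, b)`; complements satisfy
#' `p(a, b) + p(b, a) = 1`. A pair with `p >= 1/2` is *modal* in the
#' cluster.
#'
#' @param cluster a [korders_cluster()].
#' @return Data frame with columns `a`, `b`, `p` (both orientations of each
#'   canonical pair).
#' @export
marginal_proportions <- function(cluster) {
  stopifnot(inherits(cluster, "korders_cluster"))
  u <- cluster$universe
  p_ref <- marginal_ref(cluster$bits, cluster$weights)
  data.frame(a = c(u$options[u$pair_i], u$options[u$pair_j]),
             b = c(u$options[u$pair_j], u$options[u$pair_i]),
             p = c(p_ref, 1 - p_ref),
             stringsAsFactors = FALSE)
}

#' Average half distance of a relation from a cluster
#'
#' One half of the weighted average canonical distance of `rel` from the
#' cluster patterns (so that the minimum distance between distinct
#' relations is normalized to 1). Computed both from the definition and
#' from the pair-marginal identity (the sum of marginal proportions of the
#' ordered pairs *not* in `rel`); the two forms are asserted equal within
#' `1e-9`.
#'
#' @param rel a [relation()].
#' @param cluster a [korders_cluster()] over the same universe.
#' @return Nonnegative number.
#' @export
avg_half_distance <- function(rel, cluster) {
  stopifnot(inherits(rel, "relation"), inherits(cluster, "korders_cluster"))
  check_same_universe(rel$universe, cluster$universe)
  d_def <- sum(cluster$weights *
                 drop(hamming_matrix(cluster$bits, matrix(rel$bits, 1L))))
  p_ref <- marginal_ref(cluster$bits, cluster$weights)
  d_marg <- half_distance_from_marginals(rel$bits, p_ref)
  stopifnot(abs(d_def - d_marg) <= 1e-9)
  d_marg
}

#' Modal (k-modes) centroid adjustment
#'
#' Element-wise mode of the cluster: an orientation enters the new centroid
#' when its weighted proportion exceeds 1/2, stays out below 1/2, and is
#' decided by a fair coin at exactly 1/2 (using the current RNG stream).
#' The result is an asymmetric complete relation but need not be
#' transitive.
#'
#' @param cluster a [korders_cluster()] with positive total weight.
#' @return A [relation()].
#' @export
kmodes_adjust <- function(cluster) {
  stopifnot(inherits(cluster, "korders_cluster"))
  relation(cluster$universe,
           kmodes_bits(marginal_ref(cluster$bits, cluster$weights)))
}

#' Path-finding transitive centroid adjustment (TCA)
#'
#' Starting from an admissible strict linear order, repeatedly inverts a
#' free pair whose marginal proportion is below 1/2 and minimal among the
#' free pairs (ties broken deterministically by lowest canonical pair
#' index); every step strictly decreases the average half distance from the
#' cluster, and the procedure stops when all free pairs are modal. The
#' result is an admissible order and a local minimum of the cluster
#' distance. Under a monotonicity constraint the marginals of the pointwise
#' order's pairs are forced to 1, so those pairs are never inverted.
#'
#' @param start a [relation()] belonging to `constraints`.
#' @param cluster a [korders_cluster()].
#' @param constraints a [constraint_set()]; default all linear orders.
#' @return A [relation()] in the constraint set.
#' @export
tca_adjust <- function(start, cluster, constraints = constraint_set()) {
  stopifnot(inherits(start, "relation"), inherits(cluster, "korders_cluster"))
  check_same_universe(start$universe, cluster$universe)
  if (!in_constraints(start, constraints)) stop("'start' is not in the constraint set")
  p0_dir <- if (constraints$kind == "linear_orders_ma") constraints$design$p0_dir else NULL
  p_ref <- marginal_ref(cluster$bits, cluster$weights)
  relation(start$universe, tca_bits(start$bits, p_ref, start$universe, p0_dir))
}

#' Greedy transitive centroid adjustment
#'
#' Processes all ordered pairs of distinct options in decreasing order of
#' their marginal proportion in the cluster (ties broken deterministically:
#' reference orientation first, then canonical pair index, making the
#' processing order injective), inserting a pair exactly when the relation
#' stays acyclic. The final relation is a strict linear order and a local
#' minimum of the cluster distance. The start relation (default empty; the
#' pointwise order under a monotonicity constraint) is pre-inserted and
#' carried to the output.
#'
#' @param cluster a [korders_cluster()].
#' @param start optional two-column matrix of ordered option pairs to seed
#'   the relation with; must be acyclic. Overrides the constraint default.
#' @param constraints a [constraint_set()]; default all linear orders.
#' @return A [relation()] that is a strict linear order containing `start`.
#' @export
greedy_tca_adjust <- function(cluster, start = NULL,
                              constraints = constraint_set()) {
  stopifnot(inherits(cluster, "korders_cluster"))
  u <- cluster$universe
  p0_dir <- if (constraints$kind == "linear_orders_ma") constraints$design$p0_dir else NULL
  start_adj <- NULL
  if (!is.null(start)) {
    start <- as.matrix(start)
    if (nrow(start) > 0L) {
      if (!is_acyclic(start, u)) stop("'start' relation must be acyclic")
      start_adj <- matrix(FALSE, u$n, u$n)
      start_adj[cbind(option_index(u, start[, 1L]), option_index(u, start[, 2L]))] <- TRUE
    }
  }
  p_ref <- marginal_ref(cluster$bits, cluster$weights)
  relation(u, greedy_bits(p_ref, u, p0_dir, start_adj))
}
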