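#' Run k-modes / k-orders clustering
#'
#' Alternates minimum-discrepancy classification with a per-cluster
#' centroid adjustment until the overall discrepancy stops improving:
#' `method = "kmodes"` uses the element-wise modal adjustment (centroids
#' may be intransitive), `"tca"` the path-finding transitive centroid
#' adjustment started from the cluster's current centroid, and `"greedy"`
#' the greedy adjustment built from scratch (from the pointwise order under
#' a monotonicity constraint). For the two k-orders methods every final
#' centroid is a strict linear order of the constraint set.
#'
#' Initial centroids are either supplied (`init`) or generated: `k` random
#' linear orders (random permutations; random linear extensions of the
#' pointwise order under MA) for the k-orders methods, `k` relations drawn
#' uniformly from the power set of stimuli for `"kmodes"` (set
#' `init_orders = TRUE` to seed k-modes with random orders instead).
#'
#' An adjustment pass that does not improve the overall discrepancy ends
#' the run with the previous centroids kept, so the recorded discrepancy
#' trace is non-increasing. Clusters that receive no mass keep their
#' centroid during the run ("empty", flagged) and are dropped at
#' termination, as are duplicate adjusted centroids.
#'
#' @param data a [korders_dataset()].
#' @param k number of initial centroids (ignored when `init` is given).
#' @param init optional [preference_structure()] of initial centroids; for
#'   `"tca"`/`"greedy"` every state must belong to `constraints`.
#' @param method `"tca"`, `"greedy"` or `"kmodes"`.
#' @param constraints a [constraint_set()]; default all strict linear
#'   orders. Ignored by `"kmodes"` except for initialization under
#'   `init_orders = TRUE`.
#' @param tol stop when the improvement in overall discrepancy is `<= tol`
#'   (default 0: stop at no improvement; the weighted discrepancy takes
#'   finitely many values, so this terminates).
#' @param max_iter maximum number of adjustment passes.
#' @param init_orders use random linear orders to initialize `"kmodes"`.
#' @param seed optional integer seed (applied via `set.seed`).
#'
#' @return An object of class `korders_fit`: `centroids` (a
#'   [preference_structure()] whose `probs` are the final cluster mass
#'   proportions), `partition` (final [classify()] matrix), `discrepancy`,
#'   `discrepancy_trace` (one value per completed classification, non-
#'   increasing), `iterations` (adjustment passes performed), `converged`,
#'   `n_empty_dropped`, `method`, `seed`.
#' @export
run_korders <- function(data, k = NULL, init = NULL,
                        method = c("tca", "greedy", "kmodes"),
                        constraints = constraint_set(),
                        tol = 0, max_iter = 100L,
                        init_orders = FALSE, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(data, "korders_dataset"),
            inherits(constraints, "constraint_set"))
  if (!is.null(seed)) set.seed(seed)
  u <- data$universe
  if (constraints$kind == "linear_orders_ma")
    check_same_universe(u, constraints$design$universe)
  ma <- constraints$kind == "linear_orders_ma"
  p0_dir <- if (ma) constraints$design$p0_dir else NULL

  if (is.null(init)) {
    if (is.null(k) || k < 1L) stop("either 'init' or a positive 'k' is required")
    C <- init_centroid_bits(as.integer(k), u, method, constraints, init_orders)
  } else {
    stopifnot(inherits(init, "preference_structure"))
    check_same_universe(u, init$universe)
    if (method %in% c("tca", "greedy")) {
      ok <- vapply(structure_states(init), in_constraints, TRUE,
                   constraints = constraints)
      if (!all(ok)) stop("initial centroids must belong to the constraint set")
    }
    C <- init$bits
  }
  C <- C[!duplicated(bits_key(C)), , drop = FALSE]

  X <- data$bits; F_ <- data$freqs
  part <- min_discrepancy_partition(X, F_, C)
  D <- sum(F_ * part$dmin)
  trace <- D
  empty <- logical(nrow(C))
  iterations <- 0L
  converged <- FALSE

  while (iterations < max_iter) {
    newC <- C
    empty <- logical(nrow(C))
    for (c_ in seq_len(nrow(C))) {
      fc <- part$f[, c_]
      s <- sum(fc)
      if (s <= 0) { empty[c_] <- TRUE; next }
      w <- fc / s
      p_ref <- marginal_ref(X, w)
      newC[c_, ] <- switch(method,
        kmodes = kmodes_bits(p_ref),
        tca    = tca_bits(C[c_, ], p_ref, u, p0_dir),
        greedy = greedy_bits(p_ref, u, p0_dir))
    }
    newC <- newC[!duplicated(bits_key(newC)), , drop = FALSE]
    new_part <- min_discrepancy_partition(X, F_, newC)
    newD <- sum(F_ * new_part$dmin)
    iterations <- iterations + 1L
    if (D - newD > tol) {
      C <- newC; part <- new_part; D <- newD
      trace <- c(trace, newD)
    } else {
      converged <- TRUE
      break
    }
  }

  keep <- colSums(part$f) > 0
  n_empty_dropped <- sum(!keep)
  C <- C[keep, , drop = FALSE]
  part <- min_discrepancy_partition(X, F_, C)
  D <- sum(F_ * part$dmin)
  mass <- colSums(part$f)
  centroids <- preference_structure(u, C, probs = mass / sum(mass))
  f <- part$f
  class(f) <- c("partition_function", class(f))
  structure(
    list(centroids = centroids, partition = f, discrepancy = D,
         discrepancy_trace = trace, iterations = iterations,
         converged = converged, n_empty_dropped = n_empty_dropped,
         method = method, seed = seed),
    class = "korders_fit")
}

#' @export
print.korders_fit <- function(x, ...) {
  cat("k-orders fit (", x$method, "): ", structure_size(x$centroids),
      " centroids, overall discrepancy ", format(x$discrepancy),
      " after ", x$iterations, " adjustment pass(es)",
      if (x$converged) "" else " [max_iter reached]", "\n", sep = "")
  invisible(x)
}

init_centroid_bits <- function(k, universe, method, constraints, init_orders) {
  ma <- constraints$kind == "linear_orders_ma"
  if (method == "kmodes" && !init_orders) {
    return(matrix(as.integer(stats::runif(k * universe$m) < 0.5), k, universe$m))
  }
  if (ma) {
    do.call(rbind, lapply(seq_len(k), function(i)
      random_linear_extension(constraints$design)$bits))
  } else {
    do.call(rbind, lapply(seq_len(k), function(i)
      ranking_to_bits(sample.int(universe$n), universe)))
  }
}
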