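#' Respondent-level train/validation split
#'
#' Randomly assigns `floor(2N/3)` respondents to the training set and the
#' remaining `ceiling(N/3)` to the validation set, re-aggregating the
#' pattern frequencies on each side (frequencies must be integral).
#'
#' @param data a [korders_dataset()] with `N >= 3`.
#' @param seed optional integer seed.
#' @return A list with [korders_dataset()]s `train` and `validation`.
#' @export
split_train_validation <- function(data, seed = NULL) {
  stopifnot(inherits(data, "korders_dataset"))
  if (!is.null(seed)) set.seed(seed)
  if (any(abs(data$freqs - round(data$freqs)) > 1e-9))
    stop("respondent-level splitting requires integral frequencies")
  N <- as.integer(round(sum(data$freqs)))
  if (N < 3L) stop("at least 3 respondents are needed for a 2/3 - 1/3 split")
  rows <- rep(seq_len(nrow(data$bits)), times = round(data$freqs))
  rows <- sample(rows)
  n_train <- floor(2 * N / 3)
  agg <- function(r) {
    tab <- table(r)
    idx <- as.integer(names(tab))
    korders_dataset(data$universe, data$bits[idx, , drop = FALSE], as.numeric(tab))
  }
  list(train = agg(rows[seq_len(n_train)]),
       validation = agg(rows[(n_train + 1L):N]))
}

#' Incremental extension: locally optimal structures of increasing size
#'
#' Generates a sequence of fitted structures for `k = 1, 2, ...`: the
#' single-centroid solution first, then, at each step, the previous
#' solution's centroids plus one new seed state — the training pattern
#' farthest (by minimum canonical distance) from the current structure,
#' projected onto the admissible class by the greedy transitive centroid
#' adjustment of its singleton cluster (the raw pattern for
#' `method = "kmodes"`) — after which the clustering is rerun to
#' convergence. If the farthest pattern's projection duplicates an existing
#' state the next-farthest pattern is tried; the sequence stops early when
#' no new seed state can be found. The within-train overall discrepancy of
#' the sequence is non-increasing in `k`.
#'
#' @param train a [korders_dataset()].
#' @param k_max largest structure cardinality to attempt (capped at the
#'   number of distinct training patterns, with a warning).
#' @param method,constraints,tol,max_iter passed to [run_korders()].
#' @param seed optional integer seed.
#' @return A list with `structures` (list of [preference_structure()]s)
#'   and `discrepancy` (within-train overall discrepancy per candidate).
#' @export
incremental_extension <- function(train, k_max,
                                  method = c("tca", "greedy", "kmodes"),
                                  constraints = constraint_set(),
                                  tol = 0, max_iter = 100L, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(train, "korders_dataset"))
  if (!is.null(seed)) set.seed(seed)
  k_max <- as.integer(k_max)
  if (k_max < 1L) stop("'k_max' must be at least 1")
  if (k_max > nrow(train$bits)) {
    warning("'k_max' exceeds the number of distinct training patterns; capped")
    k_max <- nrow(train$bits)
  }
  u <- train$universe
  ma <- constraints$kind == "linear_orders_ma"
  p0_dir <- if (ma) constraints$design$p0_dir else NULL

  project_pattern <- function(bits) {
    if (method == "kmodes") return(bits)
    # greedy TCA on the singleton cluster concentrated on the pattern
    greedy_bits(1 - bits, u, p0_dir)
  }

  structures <- vector("list", k_max)
  discrepancy <- numeric(k_max)
  fit <- run_korders(train, k = 1L, method = method, constraints = constraints,
                     tol = tol, max_iter = max_iter)
  structures[[1L]] <- fit$centroids
  discrepancy[1L] <- fit$discrepancy
  n_done <- 1L
  for (k in seq_len(k_max)[-1L]) {
    cur <- structures[[k - 1L]]$bits
    dmin <- 2 * do.call(pmin, as.data.frame(hamming_matrix(train$bits, cur)))
    seen <- bits_key(cur)
    new_bits <- NULL
    for (cand in order(-dmin)) {
      if (dmin[cand] == 0) break   # every pattern already coincides with a state
      proj <- project_pattern(train$bits[cand, ])
      if (!(bits_key(matrix(proj, 1L)) %in% seen)) { new_bits <- proj; break }
    }
    if (is.null(new_bits)) break
    init <- preference_structure(u, rbind(cur, new_bits))
    fit <- run_korders(train, init = init, method = method,
                       constraints = constraints, tol = tol,
                       max_iter = max_iter)
    structures[[k]] <- fit$centroids
    discrepancy[k] <- fit$discrepancy
    n_done <- k
  }
  list(structures = structures[seq_len(n_done)],
       discrepancy = discrepancy[seq_len(n_done)])
}

#' Select the best candidate structure by the max-distance criterion
#'
#' For each candidate structure `P` the two average minimum discrepancies
#' `d1 = delta(V, P)` and `d2 = delta(P, V)` are computed against the
#' evaluation patterns `V` (the *distinct* patterns of the evaluation data
#' set, or frequency-weighted when `weighted = TRUE`), and the criterion is
#' their maximum `M = max(d1, d2)`. The candidate with the smallest `M`
#' wins; ties go to the smallest cardinality (parsimony).
#'
#' @param candidates list of [preference_structure()]s.
#' @param eval_data a [korders_dataset()] (validation set, or the training
#'   set itself for the training-criterion variant).
#' @param weighted weight `d1` by pattern frequencies instead of treating
#'   the evaluation patterns as a set.
#' @return A list of class `korders_selection`: `best_structure`,
#'   `best_index`, `best_M` and `table` (one row per candidate with
#'   cardinality, `d1`, `d2`, `M`).
#' @export
select_best <- function(candidates, eval_data, weighted = FALSE) {
  stopifnot(length(candidates) > 0L, inherits(eval_data, "korders_dataset"))
  u <- eval_data$universe
  V <- eval_data$bits
  tab <- data.frame(k = integer(0), cardinality = integer(0),
                    d1 = numeric(0), d2 = numeric(0), M = numeric(0))
  for (i in seq_along(candidates)) {
    P <- candidates[[i]]
    stopifnot(inherits(P, "preference_structure"))
    check_same_universe(P$universe, u)
    H <- hamming_matrix(V, P$bits)
    dmin_VP <- 2 * do.call(pmin, as.data.frame(H))
    d1 <- if (weighted) sum(eval_data$freqs * dmin_VP) / sum(eval_data$freqs)
          else mean(dmin_VP)
    d2 <- mean(2 * do.call(pmin, as.data.frame(t(H))))
    tab[i, ] <- list(i, nrow(P$bits), d1, d2, max(d1, d2))
  }
  best <- which.min(tab$M)   # first minimum = smallest k on ties
  structure(list(best_structure = candidates[[best]], best_index = best,
                 best_M = tab$M[best], table = tab),
            class = "korders_selection")
}

#' @export
print.korders_selection <- function(x, ...) {
  cat("Structure selection over", nrow(x$table), "candidates: best M =",
      format(x$best_M), "at cardinality",
      x$table$cardinality[x$best_index], "\n")
  invisible(x)
}

#' Cross-validated structure extraction and selection
#'
#' The full selection pipeline: repeatedly partition the sample into a
#' training set (two-thirds) and a validation set (one-third), grow a
#' sequence of candidate structures on each training set by
#' [incremental_extension()], score every candidate of every partition
#' with the max-distance criterion of [select_best()] — against the
#' validation set (`criterion = "validation"`) or against the training set
#' itself (`"train"`) — and return the overall best structure.
#'
#' @param data a [korders_dataset()].
#' @param k_max largest candidate cardinality per partition.
#' @param n_partitions number of random train/validation partitions.
#' @param method,constraints,tol,max_iter passed to [run_korders()].
#' @param criterion `"validation"` or `"train"`.
#' @param weighted passed to [select_best()].
#' @param seed optional integer seed.
#' @return A list of class `korders_selection` with the overall
#'   `best_structure`, `best_M`, and a `table` with one row per
#'   (partition, candidate).
#' @export
korders_select <- function(data, k_max, n_partitions = 1L,
                           method = c("tca", "greedy", "kmodes"),
                           constraints = constraint_set(),
                           criterion = c("validation", "train"),
                           tol = 0, max_iter = 100L,
                           weighted = FALSE, seed = NULL) {
  method <- match.arg(method)
  criterion <- match.arg(criterion)
  if (!is.null(seed)) set.seed(seed)
  all_tab <- NULL
  best <- NULL
  for (part in seq_len(n_partitions)) {
    sp <- split_train_validation(data)
    ext <- incremental_extension(sp$train, k_max, method = method,
                                 constraints = constraints, tol = tol,
                                 max_iter = max_iter)
    eval_data <- if (criterion == "validation") sp$validation else sp$train
    sel <- select_best(ext$structures, eval_data, weighted = weighted)
    tab <- cbind(partition = part, sel$table)
    all_tab <- rbind(all_tab, tab)
    if (is.null(best) || sel$best_M < best$best_M)
      best <- list(best_structure = sel$best_structure, best_M = sel$best_M,
                   partition = part, best_index = sel$best_index)
  }
  structure(list(best_structure = best$best_structure, best_M = best$best_M,
                 best_index = which(all_tab$partition == best$partition)[best$best_index],
                 n_partitions = n_partitions, table = all_tab),
            class = "korders_selection")
}
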