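#' Random preference structures
#'
#' Draws `n_states` distinct random preference states. Over a plain
#' [pair_universe()] each state is the strict linear order of a uniformly
#' random permutation of the options; over a [two_component_design()] each
#' state is a random linear extension of the pointwise order, so it
#' satisfies the monotonicity axiom. Duplicates are redrawn until the
#' requested number of distinct states is reached (a structure is a set).
#'
#' @param n_states number of states (`1 <= n_states <=` the number of
#'   admissible orders).
#' @param universe a [pair_universe()] or [two_component_design()].
#' @param seed optional integer seed.
#' @return A [preference_structure()] without probabilities (the uniform
#'   mixture is applied at data generation).
#' @export
random_structure <- function(n_states, universe, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_states <- as.integer(n_states)
  if (n_states < 1L) stop("'n_states' must be at least 1")
  two_comp <- inherits(universe, "two_component_design")
  u <- as_universe(universe)
  if (!two_comp && n_states > factorial(u$n))
    stop("more states requested than linear orders exist")
  draw <- function() {
    if (two_comp) random_linear_extension(universe)$bits
    else ranking_to_bits(sample.int(u$n), u)
  }
  bits <- matrix(0L, 0L, u$m)
  tries <- 0L
  while (nrow(bits) < n_states) {
    bits <- rbind(bits, draw())
    bits <- bits[!duplicated(bits_key(bits)), , drop = FALSE]
    tries <- tries + 1L
    if (tries > 1000L * n_states)
      stop("could not draw the requested number of distinct states")
  }
  preference_structure(u, bits)
}

#' Random linear extension of the pointwise order
#'
#' Starts from the design's pointwise order `P0` and repeatedly picks,
#' uniformly at random among the currently incomparable ordered pairs whose
#' insertion keeps the relation transitive, one pair to add (removing both
#' orientations of that stimulus from the incomparable set) until no
#' incomparable pair remains. The result is a strict linear order
#' containing `P0`, hence satisfying the monotonicity axiom, and is
#' transitive at every intermediate step. Note this procedural sampling is
#' not the uniform distribution over all linear extensions.
#'
#' @param design a [two_component_design()].
#' @param seed optional integer seed.
#' @return A [relation()].
#' @export
random_linear_extension <- function(design, seed = NULL) {
  stopifnot(inherits(design, "two_component_design"))
  if (!is.null(seed)) set.seed(seed)
  u <- design$universe
  n <- u$n
  P <- matrix(FALSE, n, n)
  cmp <- !is.na(design$p0_dir)
  a0 <- ifelse(design$p0_dir[cmp] == 0L, u$pair_i[cmp], u$pair_j[cmp])
  b0 <- ifelse(design$p0_dir[cmp] == 0L, u$pair_j[cmp], u$pair_i[cmp])
  P[cbind(a0, b0)] <- TRUE
  inc <- which(is.na(design$p0_dir))   # canonical indices of incomparable stimuli
  while (length(inc) > 0L) {
    cand_a <- c(u$pair_i[inc], u$pair_j[inc])
    cand_b <- c(u$pair_j[inc], u$pair_i[inc])
    valid <- vapply(seq_along(cand_a), function(t) {
      i <- cand_a[t]; j <- cand_b[t]
      # P u {(i,j)} transitive: predecessors of i precede j, successors of j follow i
      !any(P[, i] & !P[, j]) && !any(P[j, ] & !P[i, ])
    }, TRUE)
    pick <- sample(which(valid), 1L)
    P[cand_a[pick], cand_b[pick]] <- TRUE
    inc <- inc[inc != u$pair_id[cand_a[pick], cand_b[pick]]]
  }
  relation(u, as.integer(!P[cbind(u$pair_i, u$pair_j)]))
}

#' Per-pair response inversion probabilities
#'
#' Builds the error model of the data generator: for every *ordered* pair
#' `(a, b)` an inversion probability `beta_ab` (the chance that a
#' respondent whose state contains `(a, b)` answers `(b, a)` on that
#' stimulus), drawn independently and uniformly in the half-open interval
#' `(lo, hi]`. The interval `c(0, 0)` is the no-error condition (all
#' `beta = 0`).
#'
#' @param universe a [pair_universe()] or [two_component_design()].
#' @param interval numeric `c(lo, hi)` with `0 <= lo <= hi <= 0.5`.
#' @param seed optional integer seed.
#' @return An object of class `error_model` with `beta_ref`/`beta_rev`
#'   (inversion probabilities of the reference and reversed orientation of
#'   each canonical pair) and `interval`.
#' @export
sample_betas <- function(universe, interval, seed = NULL) {
  universe <- as_universe(universe)
  if (!is.null(seed)) set.seed(seed)
  interval <- as.numeric(interval)
  if (length(interval) != 2L || interval[1L] < 0 || interval[2L] > 0.5 ||
      interval[1L] > interval[2L])
    stop("'interval' must be c(lo, hi) with 0 <= lo <= hi <= 0.5")
  lo <- interval[1L]; hi <- interval[2L]
  draw <- function() {
    if (hi == lo) rep(lo, universe$m)
    else hi - stats::runif(universe$m) * (hi - lo)   # uniform in (lo, hi]
  }
  error_model(universe, draw(), draw(), interval = interval)
}

#' Assemble an error model from explicit inversion probabilities
#'
#' @param universe a [pair_universe()] or [two_component_design()].
#' @param beta_ref,beta_rev inversion probability of the reference /
#'   reversed orientation of each canonical pair, in `[0, 1]`.
#' @param interval optional interval the betas were drawn from.
#' @return An object of class `error_model`.
#' @export
error_model <- function(universe, beta_ref, beta_rev, interval = NULL) {
  universe <- as_universe(universe)
  beta_ref <- as.numeric(beta_ref); beta_rev <- as.numeric(beta_rev)
  if (length(beta_ref) != universe$m || length(beta_rev) != universe$m ||
      any(c(beta_ref, beta_rev) < 0) || any(c(beta_ref, beta_rev) > 1))
    stop("betas must be probabilities, one per canonical pair and orientation")
  structure(list(universe = universe, beta_ref = beta_ref,
                 beta_rev = beta_rev, interval = interval),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat("Error model on", x$universe$m, "stimuli; beta range [",
      format(min(c(x$beta_ref, x$beta_rev)), digits = 3), ",",
      format(max(c(x$beta_ref, x$beta_rev)), digits = 3), "]\n")
  invisible(x)
}

#' Simulate an FCPC data set from a preference structure
#'
#' Draws `N` i.i.d. respondents: each respondent's latent state is sampled
#' from the structure (uniformly, or by the structure's probabilities when
#' present) and the observed response inverts each of the state's ordered
#' pairs independently with that pair's inversion probability.
#'
#' @param structure a [preference_structure()].
#' @param error an [error_model()] (use `sample_betas(u, c(0, 0))` for
#'   noise-free data).
#' @param N number of respondents.
#' @param seed optional integer seed.
#' @return A list with `data` (a [korders_dataset()] of aggregated
#'   patterns), `labels` (latent state index per respondent) and
#'   `responses` (the N-by-m respondent-level response matrix).
#' @export
generate_dataset <- function(structure, error, N, seed = NULL) {
  stopifnot(inherits(structure, "preference_structure"),
            inherits(error, "error_model"))
  check_same_universe(structure$universe, error$universe)
  if (!is.null(seed)) set.seed(seed)
  N <- as.integer(N)
  if (N < 1L) stop("'N' must be at least 1")
  k <- nrow(structure$bits)
  probs <- if (is.null(structure$probs)) rep(1 / k, k) else structure$probs
  labels <- sample.int(k, N, replace = TRUE, prob = probs)
  S <- structure$bits[labels, , drop = FALSE]
  m <- structure$universe$m
  B0 <- matrix(error$beta_ref, N, m, byrow = TRUE)
  B1 <- matrix(error$beta_rev, N, m, byrow = TRUE)
  p_flip <- ifelse(S == 0L, B0, B1)
  flips <- matrix(stats::runif(N * m), N, m) < p_flip
  responses <- (S + flips) %% 2L
  storage.mode(responses) <- "integer"
  list(data = dataset_from_responses(structure$universe, responses),
       labels = labels, responses = responses)
}
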