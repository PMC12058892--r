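#' BLIM parameters for preference structures
#'
#' The basic local independence model (BLIM) treats the states of a
#' preference structure as latent classes with occurrence probabilities
#' `pi`, and attaches to every *ordered* pair `(a, b)` one error parameter:
#' the probability `beta_(a,b)` of observing the inverse response `(b, a)`
#' when the latent state contains `(a, b)`. The usual false-positive rate
#' is determined by the coupling `eta_(a,b) = beta_(b,a)`, which the
#' parameterization enforces structurally — there is a single stored
#' parameter per orientation, `2 * m` in total over `m` stimuli (6
#' parameters for 3 options).
#'
#' @param universe a [pair_universe()] or [two_component_design()].
#' @param pi state probabilities (nonnegative, sum 1).
#' @param beta_ref,beta_rev error probability of the reference / reversed
#'   orientation of each canonical pair, in `[0, 1]`.
#' @return An object of class `blim_params`.
#' @export
blim_params <- function(universe, pi, beta_ref, beta_rev) {
  universe <- as_universe(universe)
  pi <- as.numeric(pi)
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-9)
    stop("'pi' must be nonnegative and sum to 1")
  beta_ref <- as.numeric(beta_ref); beta_rev <- as.numeric(beta_rev)
  if (length(beta_ref) != universe$m || length(beta_rev) != universe$m ||
      any(c(beta_ref, beta_rev) < 0) || any(c(beta_ref, beta_rev) > 1))
    stop("betas must be probabilities, one per canonical pair and orientation")
  structure(list(universe = universe, pi = pi,
                 beta_ref = beta_ref, beta_rev = beta_rev),
            class = "blim_params")
}

#' Error parameter of one ordered pair
#'
#' Convenience accessor: `beta_(a,b)`, the probability of observing
#' `(b, a)` given that the state contains `(a, b)` (equivalently
#' `eta_(b,a)`).
#'
#' @param params a [blim_params()] (or an [error_model()]).
#' @param a,b option labels.
#' @return A probability.
#' @export
pair_beta <- function(params, a, b) {
  u <- params$universe
  idx <- option_index(u, c(a, b))
  j <- u$pair_id[idx[1L], idx[2L]]
  if (j == 0L) stop("not a pair of distinct options")
  if (idx[1L] < idx[2L]) params$beta_ref[j] else params$beta_rev[j]
}

# log P(bit = 0 | state) and log P(bit = 1 | state) per state and pair
blim_logcond_tables <- function(S, beta_ref, beta_rev) {
  # floor at log(1e-300) so that zero error rates stay finite in the
  # matrix products (a pattern never contributes 0 * -Inf)
  lg <- function(p) log(pmax(p, 1e-300))
  lb0 <- lg(beta_ref); l1b0 <- lg(1 - beta_ref)
  lb1 <- lg(beta_rev); l1b1 <- lg(1 - beta_rev)
  k <- nrow(S); m <- ncol(S)
  M0 <- matrix(0, k, m); M1 <- matrix(0, k, m)
  ref <- S == 0L
  M0[ref] <- matrix(l1b0, k, m, byrow = TRUE)[ref]    # state ref, observed ref
  M1[ref] <- matrix(lb0, k, m, byrow = TRUE)[ref]     # state ref, observed rev
  M0[!ref] <- matrix(lb1, k, m, byrow = TRUE)[!ref]   # state rev, observed ref
  M1[!ref] <- matrix(l1b1, k, m, byrow = TRUE)[!ref]  # state rev, observed rev
  list(M0 = M0, M1 = M1)
}

blim_logcond <- function(X, S, beta_ref, beta_rev) {
  tabs <- blim_logcond_tables(S, beta_ref, beta_rev)
  (1 - X) %*% t(tabs$M0) + X %*% t(tabs$M1)   # P x k matrix of log P(X|K)
}

#' Conditional response probability under the BLIM
#'
#' `P(R | P)`: the product, over stimuli, of the per-pair error or
#' non-error probability under local independence — e.g. with
#' `R = {(a,b),(b,c),(c,a)}` and state `P = {(b,a),(b,c),(a,c)}` the value
#' is `beta_(b,a) * (1 - beta_(b,c)) * beta_(a,c)`.
#'
#' @param pattern,state [relation()]s over the parameter universe.
#' @param params a [blim_params()].
#' @return A probability.
#' @export
blim_conditional <- function(pattern, state, params) {
  stopifnot(inherits(pattern, "relation"), inherits(state, "relation"),
            inherits(params, "blim_params"))
  check_same_universe(pattern$universe, params$universe)
  check_same_universe(state$universe, params$universe)
  exp(drop(blim_logcond(matrix(pattern$bits, 1L), matrix(state$bits, 1L),
                        params$beta_ref, params$beta_rev)))
}

#' Marginal response probability under the BLIM
#'
#' `P(X) = sum_K P(X | K) pi_K`, the mixture over the structure's states.
#'
#' @param pattern a [relation()].
#' @param structure a [preference_structure()] whose states are the latent
#'   classes (`params$pi` must have one entry per state).
#' @param params a [blim_params()].
#' @return A probability.
#' @export
blim_marginal <- function(pattern, structure, params) {
  stopifnot(inherits(pattern, "relation"),
            inherits(structure, "preference_structure"),
            inherits(params, "blim_params"))
  check_same_universe(structure$universe, params$universe)
  if (length(params$pi) != nrow(structure$bits))
    stop("'pi' must have one entry per state")
  lc <- blim_logcond(matrix(pattern$bits, 1L), structure$bits,
                     params$beta_ref, params$beta_rev)
  drop(exp(lc) %*% params$pi)
}

logsumexp_rows <- function(L) {
  mx <- apply(L, 1L, max)
  mx + log(rowSums(exp(L - mx)))
}

#' Fit the BLIM by expectation-maximization
#'
#' Maximum-likelihood estimation on the pattern frequencies: the E-step
#' computes state posteriors per distinct observed pattern, the M-step
#' updates `pi` and the per-orientation error parameters by closed-form
#' expected-frequency ratios. The log-likelihood trace is non-decreasing;
#' iteration stops when the improvement falls below `tol`. Error
#' parameters are clipped to `[1e-6, 0.5 - 1e-6]` (an error rate above 1/2
#' would re-encode the state); an orientation that appears in no state has
#' zero expected denominator and keeps its current value.
#'
#' @param data a [korders_dataset()].
#' @param structure a [preference_structure()] of latent states.
#' @param init optional [blim_params()] starting point; default uniform
#'   `pi` and all error parameters 0.1.
#' @param tol stop when the log-likelihood improves by less than this.
#' @param max_iter maximum EM iterations.
#' @return An object of class `blim_fit`: `params`, `structure`, `loglik`,
#'   `loglik_trace`, `n_free_params` (`(k - 1) + 2m` under the coupling),
#'   `aic`, `aicc`, `iterations`, `converged`, `N`.
#' @export
blim_fit <- function(data, structure, init = NULL, tol = 1e-6,
                     max_iter = 2000L) {
  stopifnot(inherits(data, "korders_dataset"),
            inherits(structure, "preference_structure"))
  check_same_universe(data$universe, structure$universe)
  u <- data$universe
  X <- data$bits; F_ <- data$freqs; N <- sum(F_)
  S <- structure$bits
  k <- nrow(S); m <- ncol(S)
  eps <- 1e-6
  if (is.null(init)) {
    pi <- rep(1 / k, k)
    beta_ref <- rep(0.1, m); beta_rev <- rep(0.1, m)
  } else {
    stopifnot(inherits(init, "blim_params"))
    pi <- init$pi
    beta_ref <- pmin(pmax(init$beta_ref, eps), 0.5 - eps)
    beta_rev <- pmin(pmax(init$beta_rev, eps), 0.5 - eps)
  }
  s_ref <- 1 - S   # k x m indicator: state contains reference orientation
  loglik <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    L <- blim_logcond(X, S, beta_ref, beta_rev)
    L <- sweep(L, 2L, log(pmax(pi, 1e-300)), "+")
    lse <- logsumexp_rows(L)
    new_loglik <- sum(F_ * lse)
    post <- exp(L - lse)
    W <- post * F_                       # P x k expected pattern-state counts
    tk <- colSums(W)                     # expected class sizes
    U <- t(W) %*% X                      # k x m expected reversed-response counts
    num_ref <- colSums(s_ref * U);        den_ref <- colSums(s_ref * tk)
    num_rev <- colSums(S * (tk - U));     den_rev <- colSums(S * tk)
    upd <- function(old, num, den)
      ifelse(den > 0, pmin(pmax(num / den, eps), 0.5 - eps), old)
    beta_ref <- upd(beta_ref, num_ref, den_ref)
    beta_rev <- upd(beta_rev, num_rev, den_rev)
    pi <- tk / N
    improved <- new_loglik - loglik
    trace <- c(trace, new_loglik)
    loglik <- new_loglik
    if (iter > 1L && improved < tol) { converged <- TRUE; break }
  }
  # log-likelihood under the final (post-M-step) parameters
  L <- blim_logcond(X, S, beta_ref, beta_rev)
  L <- sweep(L, 2L, log(pmax(pi, 1e-300)), "+")
  loglik <- sum(F_ * logsumexp_rows(L))
  n_free <- (k - 1L) + 2L * m
  aic <- -2 * loglik + 2 * n_free
  aicc <- if (N > n_free + 1) aic + 2 * n_free * (n_free + 1) / (N - n_free - 1)
          else NA_real_
  structure(
    list(params = blim_params(u, pi, beta_ref, beta_rev),
         structure = structure, loglik = loglik, loglik_trace = trace,
         n_free_params = n_free, aic = aic, aicc = aicc,
         iterations = iter, converged = converged, N = N),
    class = "blim_fit")
}

#' @export
print.blim_fit <- function(x, ...) {
  cat("BLIM fit: ", nrow(x$structure$bits), " states, logLik ",
      format(x$loglik), ", AIC ", format(x$aic), ", AICc ", format(x$aicc),
      " (", x$iterations, " EM iterations",
      if (x$converged) "" else ", not converged", ")\n", sep = "")
  invisible(x)
}

#' Simulate responses from a fitted or specified BLIM
#'
#' @param structure a [preference_structure()].
#' @param params a [blim_params()] with one `pi` per state.
#' @param N number of respondents.
#' @param seed optional integer seed.
#' @return A [korders_dataset()].
#' @export
blim_simulate <- function(structure, params, N, seed = NULL) {
  stopifnot(inherits(params, "blim_params"))
  st <- preference_structure(structure$universe, structure$bits,
                             probs = params$pi / sum(params$pi))
  em <- error_model(params$universe, params$beta_ref, params$beta_rev)
  generate_dataset(st, em, N, seed = seed)$data
}

#' Parametric-bootstrap goodness of fit for a BLIM
#'
#' Pearson X-squared over the cell scheme "the data set's distinct observed
#' patterns plus one pooled cell for everything else". The same rule is
#' applied to every replicate (each replicate's statistic uses its own
#' observed patterns as cells), so the observed and bootstrap statistics
#' are identically constructed and the p values are calibrated: `n_boot`
#' data sets of the original size are simulated from the fitted model, each
#' is refitted, and the p value is the share of bootstrap statistics at
#' least as large as the observed one.
#'
#' @param fit a [blim_fit()].
#' @param data the [korders_dataset()] the model was fitted to.
#' @param n_boot number of bootstrap replicates (the reference analysis
#'   used 1000).
#' @param seed optional integer seed.
#' @param tol,max_iter EM settings for the replicate refits.
#' @return A list with `p_value`, `statistic` (observed X-squared) and
#'   `boot_stats`.
#' @export
blim_bootstrap_gof <- function(fit, data, n_boot = 1000L, seed = NULL,
                               tol = 1e-6, max_iter = 2000L) {
  stopifnot(inherits(fit, "blim_fit"), inherits(data, "korders_dataset"))
  if (!is.null(seed)) set.seed(seed)
  N <- sum(data$freqs)
  pearson <- function(obs_bits, obs_freqs, params) {
    lc <- blim_logcond(obs_bits, fit$structure$bits,
                       params$beta_ref, params$beta_rev)
    p_cells <- drop(exp(lc) %*% params$pi)
    other_p <- max(1 - sum(p_cells), 0)
    e <- N * p_cells
    x2 <- sum((obs_freqs - e)^2 / pmax(e, 1e-12))
    if (other_p > 0)
      x2 <- x2 + (0 - N * other_p)^2 / (N * other_p)
    x2
  }
  observed <- pearson(data$bits, data$freqs, fit$params)
  boot <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    sim <- blim_simulate(fit$structure, fit$params, N)
    refit <- blim_fit(sim, fit$structure, tol = tol, max_iter = max_iter)
    boot[b] <- pearson(sim$bits, sim$freqs, refit$params)
  }
  list(p_value = mean(boot >= observed), statistic = observed,
       boot_stats = boot)
}

#' Health/economy aggregate probabilities of a preference structure
#'
#' For a two-component design, each state resolves every *non-monotone*
#' stimulus (strict conflict between the components) either in favor of the
#' option with the less severe health level or of the one with the less
#' severe economy level. Counting those choices partitions the states into
#' the health-leaning collection (`|P_H| > |P_E|`), the economy-leaning
#' one, and equal-weight states; summing the state probabilities within
#' each collection gives the aggregate probabilities of preferring one
#' component.
#'
#' @param structure a [preference_structure()] over the design's universe.
#' @param design a [two_component_design()] whose `components` include
#'   `"health"`.
#' @param pi state probabilities; defaults to `structure$probs`.
#' @return A list with `P_health`, `P_economy`, `P_equal` and `per_state`
#'   (data frame with the per-state non-monotone counts `n_health` /
#'   `n_economy` and the class).
#' @export
health_economy_aggregates <- function(structure, design, pi = structure$probs) {
  stopifnot(inherits(structure, "preference_structure"),
            inherits(design, "two_component_design"))
  check_same_universe(structure$universe, design$universe)
  hc <- match("health", design$components)
  if (is.na(hc)) stop("the design's components do not include 'health'")
  if (is.null(pi)) stop("state probabilities are required (fit a BLIM or set probs)")
  if (length(pi) != nrow(structure$bits))
    stop("'pi' must have one entry per state")
  u <- structure$universe
  nm <- which(is.na(design$p0_dir))
  if (!length(nm)) stop("the design has no non-monotone stimuli")
  h_i <- design$comp[u$pair_i[nm], hc]
  h_j <- design$comp[u$pair_j[nm], hc]
  # bit 0 selects option i; health-leaning iff the chosen option has the
  # lower (less severe) health level
  sel_ref_health <- h_i < h_j
  B <- structure$bits[, nm, drop = FALSE]
  chose_health <- t(t(B == 0L) == sel_ref_health)
  n_health <- rowSums(chose_health)
  n_economy <- length(nm) - n_health
  cls <- ifelse(n_health > n_economy, "health",
                ifelse(n_economy > n_health, "economy", "equal"))
  list(P_health = sum(pi[cls == "health"]),
       P_economy = sum(pi[cls == "economy"]),
       P_equal = sum(pi[cls == "equal"]),
       per_state = data.frame(state = seq_len(nrow(B)),
                              n_health = n_health, n_economy = n_economy,
                              pi = pi, class = cls,
                              stringsAsFactors = FALSE))
}
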