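#' True-positive rate of an extracted structure
#'
#' The share of exactly recovered states: the size of the intersection of
#' the extracted and true structures (bitwise state identity, no
#' near-match tolerance), divided by the size of the true structure
#' (`denominator = "truth"`, the proportion of true states that the
#' extraction found — the reading consistent with the reported recovery
#' results) or of the extracted structure (`"extracted"`).
#'
#' @param extracted,truth [preference_structure()]s over the same universe.
#' @param denominator `"truth"` (default) or `"extracted"`.
#' @return A number in `[0, 1]`.
#' @export
tpr <- function(extracted, truth, denominator = c("truth", "extracted")) {
  stopifnot(inherits(extracted, "preference_structure"),
            inherits(truth, "preference_structure"))
  check_same_universe(extracted$universe, truth$universe)
  denominator <- match.arg(denominator)
  hits <- sum(bits_key(extracted$bits) %in% bits_key(truth$bits))
  hits / if (denominator == "truth") nrow(truth$bits) else nrow(extracted$bits)
}

#' Average minimum discrepancy between two structures
#'
#' `delta(A, B) = (1/|A|) * sum_{A_i in A} min_{B_j in B} |A_i delta B_j|`:
#' each state of `A` is matched to its closest state of `B` by canonical
#' distance and the minima are averaged. The index is 0 exactly when
#' `A` is a subset of `B`, and it is not symmetric. Set `half = TRUE` for
#' the half-distance variant (minimum distance between distinct relations
#' normalized to 1), provided for comparison only.
#'
#' @param a,b nonempty [preference_structure()]s over the same universe.
#' @param half divide distances by 2.
#' @return Nonnegative number.
#' @export
avg_min_discrepancy <- function(a, b, half = FALSE) {
  stopifnot(inherits(a, "preference_structure"),
            inherits(b, "preference_structure"))
  check_same_universe(a$universe, b$universe)
  H <- hamming_matrix(a$bits, b$bits)
  d <- mean(2 * do.call(pmin, as.data.frame(H)))
  if (half) d / 2 else d
}

#' Estimated probability of responding coherently with monotonicity
#'
#' For each respondent, the proportion `p_s` of *monotone* stimuli answered
#' against the dominance direction (choosing the componentwise more severe
#' option) is a violation rate of the monotonicity axiom; the statistic
#' returned is `p_hat = 1 - mean(p_s)`, the maximum-likelihood estimate of
#' the probability of a coherent response. Identical response patterns have
#' identical `p_s`, so the computation runs on the aggregated data set.
#'
#' @param data a [korders_dataset()] over the design's universe.
#' @param design a [two_component_design()] with at least one monotone
#'   stimulus.
#' @return A number in `[0, 1]`.
#' @export
ma_violation_rate <- function(data, design) {
  stopifnot(inherits(data, "korders_dataset"),
            inherits(design, "two_component_design"))
  check_same_universe(data$universe, design$universe)
  mono <- which(!is.na(design$p0_dir))
  if (!length(mono)) stop("the design has no monotone stimuli")
  dir <- design$p0_dir[mono]
  viol <- t(data$bits[, mono, drop = FALSE]) != dir   # mono x P
  p_s <- colMeans(viol)
  1 - sum(data$freqs * p_s) / sum(data$freqs)
}
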