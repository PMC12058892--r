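# Independent oracles and fixtures, deliberately computed from the
# set-of-ordered-pairs representation (not the package's bit encoding).

# The eight preference relations on {a, b, c}, keyed by their traditional
# three-bit labels, as sets of ordered pairs.
table1_sets <- function() {
  list(
    "000" = rbind(c("a","b"), c("b","c"), c("c","a")),
    "001" = rbind(c("a","b"), c("b","c"), c("a","c")),
    "010" = rbind(c("a","b"), c("c","b"), c("c","a")),
    "100" = rbind(c("b","a"), c("b","c"), c("c","a")),
    "011" = rbind(c("a","b"), c("c","b"), c("a","c")),
    "101" = rbind(c("b","a"), c("b","c"), c("a","c")),
    "110" = rbind(c("b","a"), c("c","b"), c("c","a")),
    "111" = rbind(c("b","a"), c("c","b"), c("a","c")))
}

pair_key <- function(pairs) sort(paste(pairs[, 1], pairs[, 2], sep = ">"))

rel_key <- function(rel) pair_key(relation_pairs(rel))

same_set <- function(rel, pairs) identical(rel_key(rel), pair_key(pairs))

# |A delta B| from the set representation
oracle_symdiff <- function(r1, r2) {
  k1 <- rel_key(r1); k2 <- rel_key(r2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

# transitivity by exhaustive triple check on the set representation
oracle_transitive <- function(rel) {
  p <- relation_pairs(rel)
  has <- function(a, b) any(p[, 1] == a & p[, 2] == b)
  opts <- rel$universe$options
  for (a in opts) for (b in opts) for (c_ in opts) {
    if (a != b && b != c_ && a != c_ &&
        has(a, b) && has(b, c_) && !has(a, c_)) return(FALSE)
  }
  TRUE
}

# average half distance from the definition, via set symmetric differences
oracle_half_distance <- function(rel, cluster) {
  u <- cluster$universe
  d <- 0
  for (i in seq_len(nrow(cluster$bits))) {
    ri <- relation(u, cluster$bits[i, ])
    d <- d + cluster$weights[i] * oracle_symdiff(rel, ri)
  }
  d / 2
}

# a random cluster of distinct patterns with exponential-weight mixture
random_cluster <- function(universe, n_patterns = 5L) {
  bits <- matrix(as.integer(stats::runif(n_patterns * universe$m) < 0.5),
                 n_patterns, universe$m)
  bits <- bits[!duplicated(apply(bits, 1, paste, collapse = "")), , drop = FALSE]
  w <- stats::rexp(nrow(bits))
  korders_cluster(universe, bits, w / sum(w))
}

# brute-force minimum average half distance over all strict linear orders
brute_force_order_minimum <- function(universe, cluster) {
  los <- all_linear_orders(universe)
  d <- vapply(seq_len(nrow(los)), function(i)
    avg_half_distance(relation(universe, los[i, ]), cluster), 0)
  list(min = min(d), argmin = los[d < min(d) + 1e-9, , drop = FALSE])
}
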