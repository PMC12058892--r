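u3 <- pair_universe(c("a", "b", "c"))
t1 <- lapply(table1_sets(), relation_from_pairs, universe = u3)

test_that("classification splits each pattern's mass equally among closest centroids", {
  u <- pair_universe(letters[1:4])
  set.seed(11)
  # a pattern equal to a unique centroid takes its full frequency
  c1 <- perm_to_order(u, 1:4); c2 <- perm_to_order(u, 4:1)
  data <- korders_dataset(u, list(c1), 7)
  f <- classify(data, preference_structure(u, list(c1, c2)))
  expect_equal(unclass(f)[1, ], c(7, 0))
  # equidistant from 2 of 3 centroids: F(X)/|C_X| = 5 each
  x <- flip(c1, free_pairs(c1, constraint_set())[1, ])   # distance 2 from c1
  c3 <- flip(x, free_pairs(x, constraint_set())[2, ])    # distance 2 from x
  expect_equal(symdiff_distance(x, c1), 2L)
  expect_equal(symdiff_distance(x, c3), 2L)
  expect_gt(symdiff_distance(x, c2), 2L)
  f <- classify(korders_dataset(u, list(x), 10),
                preference_structure(u, list(c1, c2, c3)))
  expect_equal(unclass(f)[1, ], c(5, 0, 5))
  # partition-function conditions on random data: f >= 0, row sums = F, total = N
  for (rep in 1:5) {
    bits <- unique(matrix(as.integer(runif(8 * u$m) < .5), 8, u$m))
    F_ <- sample(1:9, nrow(bits), replace = TRUE)
    data <- korders_dataset(u, bits, F_)
    cent <- preference_structure(u, unique(matrix(as.integer(runif(3 * u$m) < .5), 3, u$m)))
    f <- unclass(classify(data, cent))
    expect_true(all(f >= 0))
    expect_equal(rowSums(f), as.numeric(F_))
    expect_equal(sum(f), sum(F_))
  }
})

test_that("overall discrepancy is the weighted distance sum and is minimal", {
  u <- pair_universe(letters[1:3])
  L <- t1[["001"]]
  # all patterns equal to centroids -> 0
  expect_equal(overall_discrepancy(korders_dataset(u3, list(L), 5),
                                   preference_structure(u3, list(L))), 0)
  # single centroid, single pattern, F = 3, |X delta C| = 4 -> 12
  X <- t1[["010"]]
  expect_equal(symdiff_distance(X, L), 4L)
  expect_equal(overall_discrepancy(korders_dataset(u3, list(X), 3),
                                   preference_structure(u3, list(L))), 12)
  # equals the brute-force minimum over whole-pattern assignments
  set.seed(5)
  for (rep in 1:10) {
    pats <- unique(matrix(as.integer(runif(3 * 3) < .5), 3, 3))
    F_ <- sample(1:5, nrow(pats), replace = TRUE)
    cents <- unique(matrix(as.integer(runif(2 * 3) < .5), 2, 3))
    data <- korders_dataset(u3, pats, F_)
    cent <- preference_structure(u3, cents)
    D <- as.matrix(dist(rbind(pats, cents), "manhattan"))
    D <- 2 * D[seq_len(nrow(pats)), nrow(pats) + seq_len(nrow(cents)), drop = FALSE]
    grid <- do.call(expand.grid, rep(list(seq_len(nrow(cents))), nrow(pats)))
    brute <- min(apply(grid, 1, function(a) sum(F_ * D[cbind(seq_along(a), a)])))
    expect_equal(overall_discrepancy(data, cent), brute)
    expect_equal(overall_discrepancy(data, cent, classify(data, cent)), brute)
  }
})

test_that("the modal adjustment is the element-wise majority and can be intransitive", {
  # a single-pattern cluster returns that pattern
  cl <- korders_cluster(u3, list(t1[["011"]]), 1)
  expect_equal(kmodes_adjust(cl)$bits, t1[["011"]]$bits)
  # Condorcet cycle: three linear orders whose majority is the 3-cycle 000
  cl <- korders_cluster(u3, list(t1[["001"]], t1[["010"]], t1[["100"]]),
                        rep(1 / 3, 3))
  mode_rel <- kmodes_adjust(cl)
  expect_true(same_set(mode_rel, table1_sets()[["000"]]))
  expect_false(is_transitive(mode_rel))
  # weighted fractional proportions match hand computation
  cl <- korders_cluster(u3, list(t1[["001"]], t1[["110"]]), c(.75, .25))
  # pair-wise majorities: (a,b) .75, (b,c) .75, (a,c) .75 -> equals 001
  expect_equal(kmodes_adjust(cl)$bits, t1[["001"]]$bits)
})

test_that("marginal proportions sum to one over the two orientations", {
  cl <- korders_cluster(u3, list(t1[["001"]], t1[["010"]]), c(.6, .4))
  mp <- marginal_proportions(cl)
  get_p <- function(a, b) mp$p[mp$a == a & mp$b == b]
  expect_equal(get_p("b", "c"), .6)
  expect_equal(get_p("a", "b"), 1)
  expect_equal(get_p("c", "a"), .4)
  for (i in seq_len(nrow(mp)))
    expect_equal(mp$p[i] + get_p(mp$b[i], mp$a[i]), 1)
  # single-pattern cluster: all marginals 0 or 1
  mp1 <- marginal_proportions(korders_cluster(u3, list(t1[["101"]]), 1))
  expect_true(all(mp1$p %in% c(0, 1)))
})

test_that("the average half distance equals the pair-marginal form (Lemma identity)", {
  set.seed(21)
  # a weight-1 member has distance 0
  expect_equal(avg_half_distance(t1[["011"]],
                                 korders_cluster(u3, list(t1[["011"]]), 1)), 0)
  for (n in 3:6) {
    u <- pair_universe(letters[seq_len(n)])
    for (rep in 1:20) {
      cl <- random_cluster(u, 6L)
      r <- relation(u, as.integer(runif(u$m) < .5))
      d <- avg_half_distance(r, cl)   # internally asserts both forms agree
      expect_equal(d, oracle_half_distance(r, cl), tolerance = 1e-9)
    }
  }
})

test_that("flipping a pair changes the half distance by p(a,b) - p(b,a)", {
  set.seed(22)
  u <- pair_universe(letters[1:4])
  cs <- constraint_set()
  for (rep in 1:10) {
    cl <- random_cluster(u, 5L)
    mp <- marginal_proportions(cl)
    L <- perm_to_order(u, sample.int(4))
    fp <- free_pairs(L, cs)
    for (i in seq_len(nrow(fp))) {
      a <- fp[i, 1]; b <- fp[i, 2]
      p_ab <- mp$p[mp$a == a & mp$b == b]
      expect_equal(avg_half_distance(flip(L, c(a, b)), cl),
                   avg_half_distance(L, cl) - (1 - p_ab) + p_ab,
                   tolerance = 1e-9)
    }
  }
})

test_that("path-finding TCA strictly descends to an all-modal local minimum", {
  set.seed(31)
  for (n in 4:5) {
    u <- pair_universe(letters[seq_len(n)])
    cs <- constraint_set()
    # cluster concentrated on one linear order: TCA reaches it from any start
    L <- perm_to_order(u, sample.int(n))
    conc <- korders_cluster(u, list(L), 1)
    for (rep in 1:5) {
      start <- perm_to_order(u, sample.int(n))
      expect_equal(tca_adjust(start, conc, cs)$bits, L$bits)
    }
    # brute force confirms L is the unique global minimum
    bf <- brute_force_order_minimum(u, conc)
    expect_equal(nrow(bf$argmin), 1L)
    expect_equal(as.integer(bf$argmin[1, ]), L$bits)
    # random clusters: monotone improvement and exhaustive local-minimum check
    for (rep in 1:10) {
      cl <- random_cluster(u, 6L)
      start <- perm_to_order(u, sample.int(n))
      out <- tca_adjust(start, cl, cs)
      expect_true(in_constraints(out, cs))
      expect_lte(avg_half_distance(out, cl), avg_half_distance(start, cl) + 1e-12)
      d_out <- avg_half_distance(out, cl)
      for (nb in neighbors(out, cs))
        expect_lte(d_out, avg_half_distance(nb, cl) + 1e-9)
      # an all-modal start is a termination point
      expect_equal(tca_adjust(out, cl, cs)$bits, out$bits)
    }
  }
})

test_that("greedy TCA yields admissible linear orders that are local minima", {
  set.seed(32)
  for (n in 4:5) {
    u <- pair_universe(letters[seq_len(n)])
    cs <- constraint_set()
    # concentrated cluster: the greedy reconstruction recovers the order
    L <- perm_to_order(u, sample.int(n))
    expect_equal(greedy_tca_adjust(korders_cluster(u, list(L), 1))$bits, L$bits)
    for (rep in 1:10) {
      cl <- random_cluster(u, 6L)
      out <- greedy_tca_adjust(cl)
      expect_true(is_transitive(out))
      d_out <- avg_half_distance(out, cl)
      for (nb in neighbors(out, cs))
        expect_lte(d_out, avg_half_distance(nb, cl) + 1e-9)
    }
  }
  # under MA the output contains P0 (and a supplied acyclic start is kept)
  d <- two_component_design(3, 3)
  csma <- constraint_set("linear_orders_ma", d)
  for (rep in 1:5) {
    cl <- random_cluster(d$universe, 8L)
    out <- greedy_tca_adjust(cl, constraints = csma)
    expect_true(in_constraints(out, csma))
    out2 <- greedy_tca_adjust(cl, start = pointwise_order(d))
    expect_true(satisfies_ma(out2, d))
  }
  expect_error(greedy_tca_adjust(random_cluster(u3, 4L),
                                 start = rbind(c("a","b"), c("b","c"), c("c","a"))),
               "acyclic")
})

test_that("the modal centroid is never farther from its cluster than a transitive one", {
  set.seed(33)
  u <- pair_universe(letters[1:5])
  for (rep in 1:10) {
    cl <- random_cluster(u, 7L)
    d_mode <- avg_half_distance(kmodes_adjust(cl), cl)
    start <- perm_to_order(u, sample.int(5))
    expect_lte(d_mode, avg_half_distance(tca_adjust(start, cl), cl) + 1e-9)
    expect_lte(d_mode, avg_half_distance(greedy_tca_adjust(cl), cl) + 1e-9)
  }
})

test_that("noise-free data with the true initialization is a fixed point", {
  set.seed(41)
  u <- pair_universe(letters[1:6])
  truth <- random_structure(2, u)
  noise_free <- sample_betas(u, c(0, 0))
  data <- generate_dataset(truth, noise_free, 60)$data
  for (method in c("tca", "greedy", "kmodes")) {
    fit <- run_korders(data, init = truth, method = method)
    expect_equal(fit$iterations, 1L)
    expect_true(fit$converged)
    expect_equal(sort(bits_key(fit$centroids$bits)), sort(bits_key(truth$bits)))
    expect_equal(fit$discrepancy, 0)
  }
})

test_that("the discrepancy trace is non-increasing for every method and seed", {
  set.seed(42)
  u <- pair_universe(letters[1:6])
  truth <- random_structure(4, u)
  data <- generate_dataset(truth, sample_betas(u, c(.1, .2)), 120)$data
  for (method in c("tca", "greedy", "kmodes")) {
    for (s in 1:3) {
      fit <- run_korders(data, k = 4, method = method, seed = s)
      expect_true(all(diff(fit$discrepancy_trace) <= 0))
      expect_true(fit$converged)
    }
  }
})

test_that("k-modes can return intransitive centroids where k-orders cannot", {
  # cyclic-majority data: heavy Condorcet mix plus a far-away order
  u <- u3
  freqs <- c(10, 10, 10)
  data <- korders_dataset(u, list(t1[["001"]], t1[["010"]], t1[["100"]]), freqs)
  fit_km <- run_korders(data, init = preference_structure(u, list(t1[["001"]])),
                        method = "kmodes", seed = 1)
  expect_false(all(vapply(structure_states(fit_km$centroids), is_transitive, TRUE)))
  for (method in c("tca", "greedy")) {
    fit <- run_korders(data, init = preference_structure(u, list(t1[["001"]])),
                       method = method, seed = 1)
    expect_true(all(vapply(structure_states(fit$centroids), is_transitive, TRUE)))
  }
})

test_that("final k-orders centroids respect the monotonicity constraint", {
  set.seed(43)
  d <- two_component_design(3, 3)
  cs <- constraint_set("linear_orders_ma", d)
  truth <- random_structure(5, d)
  data <- generate_dataset(truth, sample_betas(d, c(.1, .3)), 150)$data
  for (method in c("tca", "greedy")) {
    fit <- run_korders(data, k = 5, method = method, constraints = cs)
    ok <- vapply(structure_states(fit$centroids), in_constraints, TRUE,
                 constraints = cs)
    expect_true(all(ok))
  }
})
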