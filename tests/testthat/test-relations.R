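u3 <- pair_universe(c("a", "b", "c"))

test_that("the eight relations on three options round-trip and six are transitive", {
  sets <- table1_sets()
  rels <- lapply(sets, relation_from_pairs, universe = u3)
  # all eight distinct, and they exhaust the asymmetric complete relations
  keys <- vapply(rels, rel_key, character(3))
  expect_equal(length(unique(apply(keys, 2, paste, collapse = ";"))), 8L)
  expect_equal(nrow(all_relations(u3)), 8L)
  # set -> vector -> set round trip is the identity
  for (nm in names(sets)) {
    expect_true(same_set(rels[[nm]], sets[[nm]]))
    rt <- relation_from_pairs(u3, relation_pairs(rels[[nm]]))
    expect_equal(rt$bits, rels[[nm]]$bits)
  }
  # the only intransitive relations are the two 3-cycles
  tr <- vapply(rels, is_transitive, TRUE)
  expect_equal(sum(tr), 6L)
  expect_false(tr[["000"]])
  expect_false(tr[["111"]])
  expect_equal(unname(tr), vapply(rels, oracle_transitive, TRUE, USE.NAMES = FALSE))
})

test_that("enumerating and filtering by transitivity yields n! linear orders", {
  for (n in 2:4) {
    u <- pair_universe(letters[seq_len(n)])
    allr <- all_relations(u)
    n_trans <- sum(apply(allr, 1, function(b) is_transitive(relation(u, b))))
    expect_equal(n_trans, factorial(n))
    expect_equal(nrow(unique(all_linear_orders(u))), factorial(n))
  }
})

test_that("canonical distance is twice the Hamming distance and a metric", {
  sets <- table1_sets()
  rels <- lapply(sets, relation_from_pairs, universe = u3)
  expect_equal(symdiff_distance(rels[["001"]], rels[["001"]]), 0L)
  expect_equal(symdiff_distance(rels[["000"]], rels[["111"]]),
               oracle_symdiff(rels[["000"]], rels[["111"]]))
  expect_equal(symdiff_distance(rels[["000"]], rels[["111"]]), 6L)
  for (i in seq_along(rels)) for (j in seq_along(rels)) {
    dij <- symdiff_distance(rels[[i]], rels[[j]])
    expect_equal(dij, oracle_symdiff(rels[[i]], rels[[j]]))
    expect_equal(dij %% 2, 0)
    expect_equal(dij, symdiff_distance(rels[[j]], rels[[i]]))
    for (k in seq_along(rels))
      expect_lte(dij, symdiff_distance(rels[[i]], rels[[k]]) +
                        symdiff_distance(rels[[k]], rels[[j]]))
  }
  expect_error(symdiff_distance(rels[[1]], relation(pair_universe(c("x","y")), 0)),
               "universe")
})

test_that("the printed neighborhood of L1 is recovered at distance 2", {
  L1 <- relation_from_pairs(u3, rbind(c("b","a"), c("b","c"), c("c","a")))
  nb <- neighbors(L1, constraint_set())
  expect_length(nb, 2L)
  keys <- sort(vapply(nb, function(r) paste(rel_key(r), collapse = ";"), ""))
  expected <- sort(c(
    paste(pair_key(rbind(c("b","a"), c("c","b"), c("c","a"))), collapse = ";"),
    paste(pair_key(rbind(c("b","a"), c("b","c"), c("a","c"))), collapse = ";")))
  expect_equal(keys, expected)
  for (r in nb) expect_equal(symdiff_distance(L1, r), 2L)
})

test_that("every linear order has n - 1 neighbors and n - 1 free pairs", {
  cs <- constraint_set()
  for (n in 3:5) {
    u <- pair_universe(letters[seq_len(n)])
    set.seed(n)
    for (rep in 1:5) {
      L <- perm_to_order(u, sample.int(n))
      nb <- neighbors(L, cs)
      expect_length(nb, n - 1L)
      fp <- free_pairs(L, cs)
      expect_equal(nrow(fp), n - 1L)
      # free pairs are exactly the adjacent pairs of the ranking
      wins <- table(factor(relation_pairs(L)[, 1], levels = u$options))
      ranking <- names(sort(wins, decreasing = TRUE))
      adj <- cbind(ranking[-n], ranking[-1])
      expect_setequal(paste(fp[, 1], fp[, 2]), paste(adj[, 1], adj[, 2]))
    }
  }
})

test_that("flip inverts exactly one pair and is an involution", {
  r <- relation_from_pairs(u3, rbind(c("a","b"), c("b","c"), c("a","c")))
  flipped <- flip(r, c("a", "c"))
  expect_true(same_set(flipped, rbind(c("a","b"), c("b","c"), c("c","a"))))
  expect_false(is_transitive(flipped))
  expect_equal(flip(flipped, c("c", "a"))$bits, r$bits)
  # Table 1: flipping (a,b) in row 001 gives row 101
  r001 <- relation_from_pairs(u3, table1_sets()[["001"]])
  expect_true(same_set(flip(r001, c("a", "b")), table1_sets()[["101"]]))
  expect_error(flip(r, c("b", "a")), "not in the relation")
})

test_that("permutations map to linear orders with earlier options preferred", {
  u4 <- pair_universe(paste0("s", 1:4))
  r <- perm_to_order(u4, c(1, 3, 2, 4))
  expect_true(same_set(r, rbind(c("s1","s3"), c("s1","s2"), c("s1","s4"),
                                c("s3","s2"), c("s3","s4"), c("s2","s4"))))
  expect_true(same_set(perm_to_order(u3, 1:3), table1_sets()[["001"]]))
  keys <- apply(all_linear_orders(u4), 1, paste, collapse = "")
  expect_equal(length(unique(keys)), 24L)
  expect_error(perm_to_order(u4, c(1, 1, 2, 3)), "permutation")
})

test_that("monotone stimuli of two-component designs follow the dominance rule", {
  d44 <- two_component_design(4, 4)
  mono <- vapply(seq_len(d44$universe$m), function(j)
    is_monotone_stimulus(d44, c(d44$universe$options[d44$universe$pair_i[j]],
                                d44$universe$options[d44$universe$pair_j[j]])), TRUE)
  expect_equal(length(mono), 120L)
  expect_equal(sum(mono), 84L)
  expect_equal(sum(!mono), 36L)
  expect_true(is_monotone_stimulus(d44, c("1:2", "1:3")))   # tied first component
  d22 <- two_component_design(2, 2)
  expect_equal(sum(is.na(d22$p0_dir)), 1L)                  # only {1:2, 2:1} conflicts
})

test_that("the monotonicity axiom is equivalent to containing P0 (2x2 brute force)", {
  d <- two_component_design(2, 2)
  p0 <- pointwise_order(d)
  allr <- all_relations(d)
  contains_p0 <- function(rel) {
    k <- rel_key(rel)
    all(paste(p0[, 1], p0[, 2], sep = ">") %in% k)
  }
  n_ma <- 0L
  for (i in seq_len(nrow(allr))) {
    rel <- relation(d$universe, allr[i, ])
    expect_equal(satisfies_ma(rel, d), contains_p0(rel))
    n_ma <- n_ma + satisfies_ma(rel, d)
  }
  expect_equal(n_ma, 2L)  # the single free stimulus gives two MA relations
  # a relation containing the reverse of a P0 pair violates MA
  L <- random_linear_extension(d, seed = 1)
  expect_true(satisfies_ma(L, d))
  expect_false(satisfies_ma(flip(L, p0[1, ]), d))
})

test_that("acyclicity detection matches the cycle definition", {
  u4 <- pair_universe(letters[1:4])
  expect_true(is_acyclic(matrix(character(0), 0, 2), u4))
  expect_false(is_acyclic(rbind(c("a","b"), c("b","c"), c("c","a")), u4))
  expect_true(is_acyclic(relation_pairs(perm_to_order(u4, c(2, 4, 1, 3))), u4))
  expect_true(is_acyclic(rbind(c("a","b"), c("c","d")), u4))
})

test_that("pairs of P0 are never free under the monotonicity constraint", {
  d <- two_component_design(3, 3)
  cs <- constraint_set("linear_orders_ma", d)
  set.seed(42)
  p0_keys <- paste(pointwise_order(d)[, 1], pointwise_order(d)[, 2], sep = ">")
  for (rep in 1:5) {
    L <- random_linear_extension(d)
    fp <- free_pairs(L, cs)
    expect_false(any(paste(fp[, 1], fp[, 2], sep = ">") %in% p0_keys))
    # every free pair flip stays inside the constraint set (already checked
    # by membership), and all free pairs are adjacent pairs of the order
    for (i in seq_len(nrow(fp)))
      expect_true(in_constraints(flip(L, fp[i, ]), cs))
  }
})
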