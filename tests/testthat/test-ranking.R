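test_that("descending ranking sorts, truncates and breaks ties at random", {
  sc <- as_scores(c(a = 3, b = 2, c = 1))
  expect_equal(as.character(descending_rank(sc, 2)), c("a", "b"))

  # all-equal scores with budget n: a seeded permutation of all nodes
  eq <- as_scores(setNames(rep(1, 6), paste0("v", 1:6)))
  r1 <- descending_rank(eq, 6, rng_seed = 1)
  expect_setequal(as.character(r1), paste0("v", 1:6))
  expect_identical(as.character(descending_rank(eq, 6, rng_seed = 1)),
                   as.character(r1))
  perms <- unique(vapply(1:20, function(s)
    paste(descending_rank(eq, 6, s), collapse = ""), character(1)))
  expect_gt(length(perms), 1)

  expect_error(descending_rank(sc, 0), "budget")
  expect_error(descending_rank(sc, 4), "budget")
})

test_that("community-aware ranking follows the round-robin hand trace", {
  sc <- as_scores(c(a1 = 9, a2 = 8, a3 = 7, b1 = 5, b2 = 4))
  p <- partition(c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B"))
  expect_equal(as.character(community_aware_rank(sc, p, 4)),
               c("a1", "b1", "a2", "b2"))
  expect_equal(as.character(community_aware_rank(sc, p, 5)),
               c("a1", "b1", "a2", "b2", "a3"))
})

test_that("toy example: per-community leaders differ from global top nodes", {
  toy <- toy_example()
  expect_equal(as.character(community_aware_rank(toy$degree, toy$partition, 3)),
               c("5", "13", "19"))
  expect_equal(as.character(community_aware_rank(toy$betweenness,
                                                 toy$partition, 3)),
               c("3", "13", "21"))
  expect_setequal(as.character(descending_rank(toy$degree, 3)),
                  c("1", "4", "5"))
  expect_setequal(as.character(descending_rank(toy$betweenness, 3)),
                  c("13", "14", "15"))
})

test_that("single community degenerates to descending order", {
  set.seed(3)
  sc <- as_scores(setNames(sample(4, 8, replace = TRUE), paste0("v", 1:8)))
  p <- partition(setNames(rep("all", 8), paste0("v", 1:8)))
  for (b in c(1, 4, 8)) {
    expect_identical(as.character(community_aware_rank(sc, p, b, rng_seed = 7)),
                     as.character(descending_rank(sc, b, rng_seed = 7)))
  }
})

test_that("full-budget rankings are permutations preserving community order", {
  set.seed(9)
  nodes <- paste0("v", 1:12)
  sc <- as_scores(setNames(sample(1000, 12), nodes))
  p <- partition(setNames(rep(c("A", "B", "C"), c(5, 4, 3)), nodes))
  ca <- as.character(community_aware_rank(sc, p, 12, rng_seed = 2))
  de <- as.character(descending_rank(sc, 12, rng_seed = 2))
  expect_setequal(ca, nodes)
  expect_setequal(de, nodes)
  # within each community the order is descending in score
  for (cid in names(p$communities)) {
    mem <- ca[ca %in% p$communities[[cid]]]
    expect_true(all(diff(unclass(sc)[mem]) < 0))
  }
  # with budget <= |C|, at most one node per community
  ca3 <- as.character(community_aware_rank(sc, p, 3, rng_seed = 2))
  expect_equal(length(unique(p$assignment[ca3])), 3)
})

test_that("community-aware ranking validates inputs", {
  sc <- as_scores(c(a = 2, b = 1))
  p <- partition(c(a = "A"))
  expect_error(community_aware_rank(sc, p, 1), "'b' is missing")
  p2 <- partition(c(a = "A", b = "B"))
  expect_error(community_aware_rank(sc, p2, 3), "budget")
})

test_that("ranking matches the literal extraction-loop transcription", {
  # random instances built without score or community-size ties, so the
  # loop semantics (not tie policy) are what is compared
  set.seed(1234)
  size_sets <- list(c(4, 3, 2, 1), c(5, 3, 2), c(6, 4), c(7, 2, 1), c(5, 4, 1))
  for (i in 1:200) {
    sizes <- size_sets[[sample(length(size_sets), 1)]]
    n <- sum(sizes)
    nodes <- paste0("v", seq_len(n))
    sc <- as_scores(setNames(sample(10000, n), nodes))
    cids <- paste0("c", seq_along(sizes))
    p <- partition(setNames(rep(cids, sizes), nodes))
    budget <- sample(n, 1)
    got <- as.character(community_aware_rank(sc, p, budget, rng_seed = i))
    want <- oracle_round_robin(unclass(sc),
                               p$communities[cids],  # already size-sorted
                               budget)
    expect_identical(got, want)
  }
})
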