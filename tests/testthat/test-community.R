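test_that("communities sort by size with seeded random ties", {
  p <- partition(setNames(c(rep("A", 5), rep("B", 3), rep("C", 3)),
                          paste0("n", 1:11)))
  for (s in 1:5) {
    o <- sort_communities(p, rng_seed = s)
    expect_equal(o[1], "A")
    expect_setequal(o[2:3], c("B", "C"))
    expect_identical(o, sort_communities(p, rng_seed = s))  # deterministic
  }

  single <- partition(setNames(rep("only", 4), paste0("n", 1:4)))
  expect_equal(sort_communities(single, 1), "only")

  eq <- partition(setNames(rep(c("A", "B", "C"), each = 2), paste0("n", 1:6)))
  perms <- unique(vapply(1:40, function(s)
    paste(sort_communities(eq, s), collapse = ""), character(1)))
  for (pp in perms) {
    expect_setequal(strsplit(pp, "")[[1]], c("A", "B", "C"))
  }
  expect_gt(length(perms), 1)  # ties actually vary across seeds
})

test_that("sort_communities preserves the community set and size order", {
  set.seed(42)
  for (i in 1:20) {
    nc <- sample(2:6, 1)
    sizes <- sample(1:5, nc, replace = TRUE)
    assign <- setNames(rep(paste0("c", seq_len(nc)), sizes),
                       paste0("v", seq_len(sum(sizes))))
    p <- partition(assign)
    o <- sort_communities(p, rng_seed = i)
    expect_setequal(o, paste0("c", seq_len(nc)))
    expect_true(all(diff(lengths(p$communities)[o]) <= 0))
  }
})

test_that("mixing parameter counts inter-community edges", {
  # two triangles, no bridge: all edges internal
  g0 <- graph_from_pairs(c("1","2", "2","3", "1","3", "4","5", "5","6", "4","6"))
  p <- partition(setNames(c("A","A","A","B","B","B"), as.character(1:6)))
  expect_equal(mixing_parameter(g0, p), 0)

  # add the bridge: 1 of 7 edges crosses
  g1 <- g_two_triangles()
  expect_equal(mixing_parameter(g1, p), 1 / 7)

  # complete bipartite with sides as communities: everything crosses
  gb <- graph_from_pairs(as.vector(t(expand.grid(paste0("u", 1:3),
                                                 paste0("v", 1:3)))))
  pb <- partition(setNames(c(rep("U", 3), rep("V", 3)),
                           c(paste0("u", 1:3), paste0("v", 1:3))))
  expect_equal(mixing_parameter(gb, pb), 1)

  # merging all communities into one gives 0
  pall <- partition(setNames(rep("all", 6), as.character(1:6)))
  expect_equal(mixing_parameter(g1, pall), 0)

  # relabeling community ids changes nothing
  p2 <- partition(setNames(c("x","x","x","y","y","y"), as.character(1:6)))
  expect_equal(mixing_parameter(g1, p2), mixing_parameter(g1, p))

  expect_error(mixing_parameter(igraph::make_empty_graph(3, directed = FALSE), pall),
               "no edges")
  pmiss <- partition(setNames(c("A","A","A","B","B"), as.character(1:5)))
  expect_error(mixing_parameter(g1, pmiss), "not in the partition")
})

test_that("strength classes cover [0,1] with the documented boundaries", {
  expect_equal(classify_strength(0.08), "strong")
  expect_equal(classify_strength(0.20), "strong")
  expect_equal(classify_strength(0.21), "medium")
  expect_equal(classify_strength(0.39), "medium")
  expect_equal(classify_strength(0.40), "weak")
  expect_equal(classify_strength(1), "weak")
  expect_error(classify_strength(-0.1), "0, 1")
  expect_error(classify_strength(1.2), "0, 1")
  mus <- seq(0, 1, by = 0.001)
  expect_true(all(classify_strength(mus) %in% c("strong", "medium", "weak")))
})

test_that("community_report mirrors the partition summary", {
  g <- g_two_triangles()
  p <- partition(setNames(c("A","A","A","B","B","B"), as.character(1:6)))
  rep <- community_report(g, p)
  expect_equal(rep$n_communities, 2)
  expect_equal(rep$min_size, 3)
  expect_equal(rep$max_size, 3)
  expect_equal(rep$mu, 1 / 7)
  expect_equal(rep$strength, "strong")
})

test_that("partition constructor enforces disjoint non-empty communities", {
  expect_error(partition(setNames(c("A", "B"), c("x", "x"))), "more than once")
  expect_error(partition(c("A", "B")), "named")
  p <- as_partition(data.frame(node = c("a", "b"), comm = c(1, 2)))
  expect_equal(sort(names(p$communities)), c("1", "2"))
})
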