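test_that("epidemic threshold has its closed forms", {
  expect_equal(epidemic_threshold(igraph::make_ring(3)), 1)        # 2-regular
  expect_equal(epidemic_threshold(g_complete(5)), 1 / 3)           # 4-regular
  n <- 8
  expect_equal(epidemic_threshold(g_star(n - 1)), 2 / (n - 2))     # star
  # perfect matching: all degrees 1, undefined
  pm <- graph_from_pairs(c("1","2", "3","4"))
  expect_error(epidemic_threshold(pm), "undefined")
  expect_error(epidemic_threshold(igraph::make_empty_graph(3)), "no edges")
})

test_that("degenerate infection probabilities give exact outbreak sizes", {
  g <- g_two_cliques_bridge(4)
  r0 <- simulate_sir(g, c("a1", "b2"), lambda = 0, runs = 50, rng_seed = 1)
  expect_true(all(r0$per_run_recovered == 2))

  r1 <- simulate_sir(g, "a3", lambda = 1, recovery_prob = 1, runs = 50,
                     rng_seed = 1)
  expect_true(all(r1$per_run_recovered == 8))  # deterministic BFS wave

  rall <- simulate_sir(g, igraph::V(g)$name, lambda = 0.3, runs = 20,
                       rng_seed = 1)
  expect_true(all(rall$per_run_recovered == 8))
})

test_that("simulation is reproducible and validates inputs", {
  g <- g_random(20, 0.2, seed = 2)
  a <- simulate_sir(g, "1", lambda = 0.4, runs = 40, rng_seed = 99)
  b <- simulate_sir(g, "1", lambda = 0.4, runs = 40, rng_seed = 99)
  expect_identical(a$per_run_recovered, b$per_run_recovered)
  expect_identical(a$steps, b$steps)
  expect_error(simulate_sir(g, character(0), 0.5), "empty seed")
  expect_error(simulate_sir(g, "zz", 0.5), "not in graph")
  expect_error(simulate_sir(g, "1", 1.5), "lambda")
  expect_error(simulate_sir(g, "1", 0.5, recovery_prob = 0), "recovery_prob")
})

test_that("center-seeded 3-path outbreak matches exact enumeration", {
  # seed = center, lambda = 1/2, one-step recovery: each leaf is reached
  # independently with probability 1/2, so P(R = 1,2,3) = (1/4, 1/2, 1/4)
  g <- g_path(3)
  runs <- 20000
  r <- simulate_sir(g, "2", lambda = 0.5, recovery_prob = 1, runs = runs,
                    rng_seed = 31)
  ph <- tabulate(r$per_run_recovered, 3) / runs
  p_exact <- c(0.25, 0.5, 0.25)
  se <- sqrt(p_exact * (1 - p_exact) / runs)
  expect_true(all(abs(ph - p_exact) < 3 * se))
})

test_that("outbreak size grows with the infection probability", {
  net <- generate_planted_partition(5, 10, 0.5, 0.05, rng_seed = 4)
  g <- net$graph
  means <- vapply(c(0.1, 0.3, 0.6), function(lam) {
    simulate_sir(g, c("1", "11", "21"), lambda = lam, runs = 10000,
                 rng_seed = 77)$mean_recovered
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("gain statistic is zero for identical or saturating seed sets", {
  net <- generate_planted_partition(3, 5, 0.8, 0.2, rng_seed = 8)
  g <- net$graph
  sc <- compute_centrality(g, "degree")
  # single community: both schemes coincide under a shared seed
  pall <- partition(setNames(rep("all", igraph::vcount(g)),
                             igraph::V(g)$name))
  d0 <- delta_r(g, sc, pall, f_o = 0.4, lambda = 0.3, runs = 50, rng_seed = 5)
  expect_equal(d0$delta_r, 0)
  # lambda = 1 on a connected graph saturates both schemes
  d1 <- delta_r(g, sc, net$partition, f_o = 0.2, lambda = 1, runs = 50,
                rng_seed = 5)
  expect_equal(d1$delta_r, 0)
  # f_o = 1 seeds everything either way
  dall <- delta_r(g, sc, net$partition, f_o = 1, lambda = 0.2, runs = 50,
                  rng_seed = 5)
  expect_equal(dall$delta_r, 0)
})

test_that("spreading seeds across separated cliques increases the outbreak", {
  # two 4-cliques plus a bridge; scores steer the descending scheme into one
  # clique while the community-aware scheme must cover both
  g <- g_two_cliques_bridge(4)
  p <- partition(setNames(rep(c("A", "B"), each = 4),
                          c(paste0("a", 1:4), paste0("b", 1:4))))
  sc <- as_scores(c(a2 = 8, a3 = 7, a4 = 6, a1 = 5, b2 = 4, b3 = 3,
                    b4 = 2, b1 = 1))
  d <- delta_r(g, sc, p, f_o = 0.25, lambda = 0.5, recovery_prob = 1,
               runs = 10000, rng_seed = 17)
  expect_gt(d$delta_r, 0)
  expect_gt(d$mean_ca, d$mean_do)
})

test_that("both gain normalizations agree in sign and differ by scale", {
  net <- generate_planted_partition(4, 8, 0.6, 0.02, rng_seed = 12)
  g <- net$graph
  sc <- compute_centrality(g, "degree")
  dn <- delta_r(g, sc, net$partition, 0.2, lambda = 0.25, runs = 400,
                rng_seed = 3)
  do <- delta_r(g, sc, net$partition, 0.2, lambda = 0.25, runs = 400,
                rng_seed = 3, normalization = "outbreak")
  expect_equal(sign(dn$delta_r), sign(do$delta_r))
  expect_equal(do$delta_r * dn$mean_do / igraph::vcount(g), dn$delta_r,
               tolerance = 1e-9)
})
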