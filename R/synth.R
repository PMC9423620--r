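#' Generate a planted-partition random graph
#'
#' Classic stochastic block model with `q` equal-sized blocks: each
#' within-block pair is connected independently with probability `p_in`, each
#' between-block pair with `p_out`. Used as a small controlled fixture with a
#' known ground-truth partition.
#'
#' @param q Number of communities (>= 1).
#' @param size Nodes per community (>= 2).
#' @param p_in Intra-community edge probability.
#' @param p_out Inter-community edge probability, `p_out <= p_in`.
#' @param rng_seed Integer seed.
#' @return A list with elements `graph` (igraph) and `partition`
#'   ([partition] with communities `"c1"`, ..., `"cq"`).
#' @examples
#' net <- generate_planted_partition(2, 4, 1, 0, rng_seed = 7)
#' igraph::ecount(net$graph)  # two disjoint 4-cliques: 12 edges
#' @export
generate_planted_partition <- function(q, size, p_in, p_out, rng_seed = 1L) {
  if (q < 1) stop("generate_planted_partition: q must be >= 1")
  if (size < 2) stop("generate_planted_partition: size must be >= 2")
  if (p_out > p_in || p_in > 1 || p_out < 0) {
    stop("generate_planted_partition: need 0 <= p_out <= p_in <= 1")
  }
  n <- q * size
  g <- with_rng(rng_seed, {
    pm <- matrix(p_out, q, q)
    diag(pm) <- p_in
    igraph::sample_sbm(n, pref.matrix = pm, block.sizes = rep(size, q))
  })
  g <- igraph::set_vertex_attr(g, "name", value = as.character(seq_len(n)))
  part <- partition(setNames(rep(paste0("c", seq_len(q)), each = size),
                             as.character(seq_len(n))))
  list(graph = g, partition = part)
}

#' Generate an LFR-style modular benchmark graph
#'
#' Generates a graph with a planted community structure in the style of the
#' LFR benchmark: node degrees follow a truncated power law with exponent
#' `gamma` calibrated so the mean degree matches `avg_degree`; community
#' sizes follow a truncated power law with exponent `theta` on
#' `[min_community, max_community]`; each node splits its degree into an
#' internal part (within its community) and an external part so that the
#' expected fraction of inter-community edge endpoints equals the target
#' mixing parameter `mu`. Edges are wired by a configuration model inside
#' each community and globally across communities, with rewiring retries to
#' keep the graph simple.
#'
#' The returned partition is the planted ground truth. Generation is
#' deterministic given `rng_seed`; a realization whose realized mixing
#' parameter deviates from the target by more than 0.05 is rejected and
#' retried under a derived seed, up to `max_attempts` times.
#'
#' @param n Number of nodes.
#' @param avg_degree Target mean degree.
#' @param max_degree Maximum node degree.
#' @param mu Target mixing parameter, strictly between 0 and 1.
#' @param theta Community-size power-law exponent (> 1).
#' @param gamma Degree power-law exponent (> 1).
#' @param min_community,max_community Bounds on community sizes.
#' @param rng_seed Integer seed.
#' @param max_attempts Bounded retry count for rejected realizations.
#' @return A list with `graph` (igraph, simple undirected, `n` nodes),
#'   `partition` (planted [partition]), `mu` (realized mixing parameter),
#'   `target_mu` and `attempts`.
#' @examples
#' net <- generate_lfr(n = 300, avg_degree = 6, max_degree = 20, mu = 0.1,
#'                     theta = 2.7, gamma = 2.7, min_community = 10,
#'                     max_community = 60, rng_seed = 1)
#' round(net$mu, 2)
#' @export
generate_lfr <- function(n = 2500, avg_degree = 8, max_degree = 27, mu,
                         theta = 2.7, gamma = 2.7, min_community = 4,
                         max_community = 250, rng_seed = 1L,
                         max_attempts = 20L) {
  if (min_community > max_community) {
    stop("generate_lfr: min_community > max_community")
  }
  if (min_community > n || max_community > n) {
    stop("generate_lfr: community size bounds exceed n")
  }
  if (!is.finite(mu) || mu <= 0 || mu >= 1) {
    stop("generate_lfr: mu must be strictly between 0 and 1")
  }
  if (theta <= 1 || gamma <= 1) {
    stop("generate_lfr: power-law exponents must exceed 1")
  }
  if (max_degree >= n) stop("generate_lfr: max_degree must be < n")
  if (avg_degree >= max_degree) {
    stop("generate_lfr: avg_degree must be < max_degree")
  }
  for (attempt in seq_len(max_attempts)) {
    res <- try(with_rng(derive_seed(rng_seed, "lfr-attempt", attempt),
                        lfr_attempt(n, avg_degree, max_degree, mu, theta,
                                    gamma, min_community, max_community)),
               silent = TRUE)
    if (inherits(res, "try-error")) next
    if (abs(res$mu - mu) <= 0.05) {
      res$attempts <- attempt
      return(res)
    }
  }
  stop("generate_lfr: no admissible realization after ", max_attempts,
       " attempts (target mu = ", mu, ")")
}

# One generation attempt; runs inside a seeded RNG context.
lfr_attempt <- function(n, avg_degree, max_degree, mu, theta, gamma,
                        min_community, max_community) {
  ks <- sample_powerlaw_degrees(n, gamma, max_degree, avg_degree)

  sizes <- sample_community_sizes(n, theta, min_community, max_community)
  ncomm <- length(sizes)

  # Split each degree: external part by stochastic rounding of mu * k, so the
  # expected endpoint fraction crossing communities equals the target mu.
  kext <- floor(mu * ks) + as.integer(runif(n) < (mu * ks - floor(mu * ks)))
  kext <- pmin(kext, ks)
  kint <- ks - kext

  # Assign nodes to communities. A node prefers a community strictly larger
  # than its internal degree; when only smaller communities have room left
  # (common at low mu, where internal degrees approach total degrees while
  # the smallest admissible communities cannot host them) it takes the
  # largest community with remaining capacity. Process high internal degrees
  # first, drawing uniformly among eligible communities (not by remaining
  # capacity: capacity weighting would herd the hubs into the largest
  # community and manufacture a dense core the benchmark model does not
  # have).
  cap <- sizes
  memb <- integer(n)
  for (v in order(-kint, sample.int(n))) {
    elig <- which(cap > 0 & sizes > kint[v])
    if (!length(elig)) {
      avail <- which(cap > 0)
      elig <- avail[sizes[avail] == max(sizes[avail])]
    }
    j <- if (length(elig) == 1) elig else sample(elig, 1)
    memb[v] <- j
    cap[j] <- cap[j] - 1
  }

  # A node cannot have more internal links than community co-members: cap
  # internal degrees at (community size - 1) and push the surplus to the
  # external side, then convert an equal number of external stubs elsewhere
  # back to internal so the expected mixing parameter stays on target.
  csize <- sizes[memb]
  over <- pmax(kint - (csize - 1L), 0L)
  kint <- pmin(kint, csize - 1L)
  kext <- kext + over
  surplus <- sum(over)
  cand <- which(kext > 0L & over == 0L & kint < csize - 1L)
  while (surplus > 0L && length(cand)) {
    i <- if (length(cand) == 1) cand else sample(cand, 1)
    kext[i] <- kext[i] - 1L
    kint[i] <- kint[i] + 1L
    surplus <- surplus - 1L
    if (kext[i] == 0L || kint[i] >= csize[i] - 1L) cand <- setdiff(cand, i)
  }

  # Intra-community wiring: configuration model per community.
  e1 <- integer(0)
  e2 <- integer(0)
  for (j in seq_len(ncomm)) {
    mem <- which(memb == j)
    d <- pmin(kint[mem], length(mem) - 1L)
    if (sum(d) %% 2 == 1) {
      i <- sample(which(d > 0), 1)
      d[i] <- d[i] - 1L
      kext[mem[i]] <- kext[mem[i]] + 1L  # keep total degree
    }
    if (sum(d) == 0) next
    pe <- pair_stubs(rep(mem, d), forbid_same = NULL)
    e1 <- c(e1, pe[, 1])
    e2 <- c(e2, pe[, 2])
  }

  # Inter-community wiring: global configuration model over external stubs,
  # rejecting pairs that fall inside one community.
  if (sum(kext) %% 2 == 1) {
    i <- sample(which(kext > 0), 1)
    kext[i] <- kext[i] - 1L
  }
  if (sum(kext) > 0) {
    pe <- pair_stubs(rep(seq_len(n), kext), forbid_same = memb,
                     existing = cbind(e1, e2))
    e1 <- c(e1, pe[, 1])
    e2 <- c(e2, pe[, 2])
  }

  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(e1, e2))
  g <- igraph::simplify(g)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(seq_len(n)))
  part <- partition(setNames(paste0("c", memb), as.character(seq_len(n))))
  list(graph = g,
       partition = part,
       mu = mixing_parameter(g, part),
       target_mu = mu)
}

# Pair stubs (a vector of node indices, one entry per half-edge) into simple
# edges: no self-loops, no duplicate edges (including against `existing`),
# and, when `forbid_same` gives a block label per node, no pair within one
# block. Stubs that random re-pairing cannot resolve are placed by
# double-edge swaps against already-accepted edges; anything still
# unresolved after that is dropped.
pair_stubs <- function(stubs, forbid_same = NULL, existing = NULL,
                       max_rounds = 60L) {
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  seen <- character(0)
  if (!is.null(existing) && nrow(existing)) {
    seen <- ekey(existing[, 1], existing[, 2])
  }
  ok_pair <- function(a, b) {
    a != b & !(ekey(a, b) %in% seen) &
      (if (is.null(forbid_same)) TRUE else forbid_same[a] != forbid_same[b])
  }
  acc1 <- integer(0)
  acc2 <- integer(0)
  pool <- stubs
  for (round in seq_len(max_rounds)) {
    if (length(pool) < 2) break
    pool <- sample(pool)
    if (length(pool) %% 2 == 1) {
      leftover <- pool[length(pool)]
      pool <- pool[-length(pool)]
    } else {
      leftover <- integer(0)
    }
    a <- pool[seq(1, length(pool), by = 2)]
    b <- pool[seq(2, length(pool), by = 2)]
    key <- ekey(a, b)
    bad <- a == b | duplicated(key) | key %in% seen
    if (!is.null(forbid_same)) {
      bad <- bad | forbid_same[a] == forbid_same[b]
    }
    acc1 <- c(acc1, a[!bad])
    acc2 <- c(acc2, b[!bad])
    seen <- c(seen, key[!bad])
    pool <- c(a[bad], b[bad], leftover)
    if (!any(bad) && length(leftover) == 0) {
      pool <- integer(0)
      break
    }
  }
  # Swap repair: for a leftover stub pair (u, v), find an accepted edge
  # (x, y) such that replacing it with (u, x) and (v, y) keeps the graph
  # simple (and respects the block constraint); this preserves all degrees.
  while (length(pool) >= 2 && length(acc1) > 0) {
    u <- pool[1]
    v <- pool[2]
    pool <- pool[-(1:2)]
    if (isTRUE(ok_pair(u, v))) {
      acc1 <- c(acc1, u)
      acc2 <- c(acc2, v)
      seen <- c(seen, ekey(u, v))
      next
    }
    placed <- FALSE
    for (try in seq_len(min(200L, length(acc1)))) {
      e <- sample.int(length(acc1), 1)
      x <- acc1[e]
      y <- acc2[e]
      for (sw in 1:2) {
        if (sw == 2) { tmp <- x; x <- y; y <- tmp }
        if (u != x && v != y && isTRUE(ok_pair(u, x)) &&
            isTRUE(ok_pair(v, y)) && !identical(ekey(u, x), ekey(v, y))) {
          acc1[e] <- u
          acc2[e] <- x
          acc1 <- c(acc1, v)
          acc2 <- c(acc2, y)
          seen <- c(seen, ekey(u, x), ekey(v, y))
          placed <- TRUE
          break
        }
      }
      if (placed) break
    }
  }
  cbind(acc1, acc2)
}

# Integer power-law degrees on [k_min, kmax] with k_min calibrated so the
# expected value of the discretized distribution hits target_mean.
sample_powerlaw_degrees <- function(n, gamma, kmax, target_mean) {
  xmin <- solve_powerlaw_xmin(gamma, kmax, target_mean)
  k <- floor(rtrunc_pareto(n, gamma, xmin, kmax + 1))
  pmin(pmax(k, 1L), kmax)
}

# Continuous truncated Pareto sampler via inverse CDF.
rtrunc_pareto <- function(n, gamma, xmin, xmax) {
  a <- 1 - gamma
  u <- runif(n)
  (xmin^a - u * (xmin^a - xmax^a))^(1 / a)
}

# Mean of floor(X) for X ~ truncated Pareto(gamma) on [xmin, kmax + 1).
mean_floor_pareto <- function(xmin, gamma, kmax) {
  a <- 1 - gamma
  z <- xmin^a - (kmax + 1)^a
  cdf <- function(x) (xmin^a - x^a) / z
  k0 <- floor(xmin)
  ks <- k0:kmax
  lo <- pmax(ks, xmin)
  hi <- pmin(ks + 1, kmax + 1)
  sum(ks * (cdf(hi) - cdf(lo)))
}

solve_powerlaw_xmin <- function(gamma, kmax, target_mean) {
  f <- function(x) mean_floor_pareto(x, gamma, kmax) - target_mean
  if (f(1) >= 0) return(1)
  if (f(kmax - 1e-9) <= 0) {
    stop("degree sequence infeasible: target mean ", target_mean,
         " not reachable below max degree ", kmax)
  }
  uniroot(f, c(1, kmax - 1e-9), tol = 1e-10)$root
}

# Community sizes: discrete power law on [smin, smax], drawn until the total
# reaches n, then adjusted to sum exactly to n within the bounds.
sample_community_sizes <- function(n, theta, smin, smax) {
  support <- smin:smax
  w <- support^(-theta)
  cw <- cumsum(w / sum(w))
  draw <- function(k) support[findInterval(runif(k), cw) + 1L]
  sizes <- integer(0)
  while (sum(sizes) < n) {
    sizes <- c(sizes, draw(1L))
  }
  excess <- sum(sizes) - n
  if (excess > 0) {
    last <- sizes[length(sizes)]
    if (last - excess >= smin) {
      sizes[length(sizes)] <- last - excess
    } else {
      sizes <- sizes[-length(sizes)]
      deficit <- n - sum(sizes)
      if (length(sizes) == 0) {
        if (deficit < smin || deficit > smax) {
          stop("community sizes infeasible for n = ", n)
        }
        sizes <- deficit
        deficit <- 0
      }
      while (deficit > 0) {
        room <- which(sizes < smax)
        if (!length(room)) stop("community sizes infeasible for n = ", n)
        i <- if (length(room) == 1) room else sample(room, 1)
        sizes[i] <- sizes[i] + 1L
        deficit <- deficit - 1L
      }
    }
  }
  sizes
}
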