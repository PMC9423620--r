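# Independent oracles: deliberately naive implementations kept separate from
# the package code paths they check.

# Literal transcription of the community-by-community extraction loop:
# given per-community descending score lists (largest community first),
# repeatedly sweep the communities, popping one node from each non-empty
# list per sweep, cutting as soon as the budget is exhausted.
oracle_round_robin <- function(scores, comm_nodes_ordered, budget) {
  Dcl <- lapply(comm_nodes_ordered, function(members) {
    members[order(-scores[members])]
  })
  L <- character(0)
  B <- budget
  while (B != 0) {
    for (l in seq_along(Dcl)) {
      if (length(Dcl[[l]]) > 0) {
        v <- Dcl[[l]][1]
        Dcl[[l]] <- Dcl[[l]][-1]
        L <- c(L, v)
        B <- B - 1
        if (B == 0) break
      }
    }
    if (all(lengths(Dcl) == 0)) break
  }
  L
}

# Plain-R BFS all-pairs distance matrix over an adjacency (name) list.
oracle_distances <- function(g) {
  nm <- igraph::V(g)$name
  adj <- lapply(igraph::as_adj_list(g), function(v) as.integer(v))
  n <- length(nm)
  D <- matrix(Inf, n, n, dimnames = list(nm, nm))
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[!is.finite(D[s, nxt])]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

# Brute-force betweenness via shortest-path counting by dynamic programming
# over BFS layers (not the production algorithm).
oracle_betweenness <- function(g) {
  nm <- igraph::V(g)$name
  n <- length(nm)
  D <- oracle_distances(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  # sigma[s, u]: number of shortest s-u paths
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (d in sort(unique(D[s, is.finite(D[s, ])]))) {
      if (d == 0) next
      for (u in which(D[s, ] == d)) {
        pred <- which(A[, u] == 1 & D[s, ] == d - 1)
        sigma[s, u] <- sum(sigma[s, pred])
      }
    }
  }
  bc <- setNames(numeric(n), nm)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || s == v || t == v) next
      if (!is.finite(D[s, t])) next
      if (D[s, v] + D[v, t] == D[s, t]) {
        tot <- tot + sigma[s, v] * sigma[t, v] / sigma[s, t]
      }
    }
    bc[v] <- tot
  }
  bc
}

# Closeness under the per-component convention, from the BFS distances.
oracle_closeness <- function(g) {
  nm <- igraph::V(g)$name
  n <- length(nm)
  D <- oracle_distances(g)
  sapply(seq_len(n), function(v) {
    reach <- which(is.finite(D[v, ]))
    nc <- length(reach)
    if (nc <= 1 || n == 1) return(0)
    s <- sum(D[v, reach])
    (nc - 1) / (n - 1) * (nc - 1) / s
  }) |> setNames(nm)
}

# Katz scores by explicit series summation sum_k alpha^k A^k 1.
oracle_katz <- function(g, alpha, tol = 1e-10, max_terms = 10000) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  term <- rep(1, n)
  total <- rep(0, n)
  for (k in seq_len(max_terms)) {
    term <- alpha * as.numeric(A %*% term)
    total <- total + term
    if (max(abs(term)) < tol) break
  }
  setNames(total, igraph::V(g)$name)
}

# PageRank by damped power iteration to tight convergence.
oracle_pagerank <- function(g, damping = 0.85, tol = 1e-12) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  deg <- rowSums(A)
  P <- A / ifelse(deg == 0, 1, deg)
  x <- rep(1 / n, n)
  repeat {
    xn <- (1 - damping) / n + damping * as.numeric(t(P) %*% x)
    if (max(abs(xn - x)) < tol) break
    x <- xn
  }
  setNames(xn / sum(xn), igraph::V(g)$name)
}

# Helper: wrap a plain named numeric as centrality scores.
as_scores <- function(x, measure = "degree") {
  structure(as.numeric(x), names = names(x), measure = measure,
            class = "centrality_scores")
}
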