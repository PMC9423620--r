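# Small graph builders used across tests (all with character vertex names).

graph_from_pairs <- function(pairs, isolates = character(0)) {
  g <- igraph::graph_from_edgelist(matrix(as.character(pairs), ncol = 2,
                                          byrow = TRUE), directed = FALSE)
  if (length(isolates)) {
    g <- igraph::add_vertices(g, length(isolates), name = as.character(isolates))
  }
  g
}

g_path <- function(n) {
  v <- as.character(seq_len(n))
  graph_from_pairs(as.vector(rbind(v[-n], v[-1])))
}

g_star <- function(k) {  # center "c", k leaves
  graph_from_pairs(as.vector(rbind("c", paste0("l", seq_len(k)))))
}

g_complete <- function(n) {
  v <- as.character(seq_len(n))
  pr <- t(utils::combn(v, 2))
  graph_from_pairs(as.vector(t(pr)))
}

# two triangles 1-2-3 and 4-5-6 bridged by edge 3-4
g_two_triangles <- function() {
  graph_from_pairs(c("1","2", "2","3", "1","3", "4","5", "5","6", "4","6",
                     "3","4"))
}

# two k-cliques with a single bridge between node a1 and b1
g_two_cliques_bridge <- function(k = 4) {
  a <- paste0("a", seq_len(k))
  b <- paste0("b", seq_len(k))
  pr <- rbind(t(utils::combn(a, 2)), t(utils::combn(b, 2)), c("a1", "b1"))
  graph_from_pairs(as.vector(t(pr)))
}

# seeded Erdos-Renyi graph on n named nodes (plain R, for oracle tests)
g_random <- function(n, p, seed) {
  set.seed(seed)
  pr <- t(utils::combn(as.character(seq_len(n)), 2))
  keep <- stats::runif(nrow(pr)) < p
  if (!any(keep)) keep[1] <- TRUE
  graph_from_pairs(as.vector(t(pr[keep, , drop = FALSE])),
                   isolates = setdiff(as.character(seq_len(n)),
                                      unique(as.vector(pr[keep, ]))))
}
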