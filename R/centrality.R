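#' Supported centrality measures
#'
#' Six classical measures spanning three families: neighborhood-based (degree,
#' maximum neighborhood component), path-based (betweenness, closeness) and
#' iterative refinement-based (Katz, PageRank).
#'
#' @return Character vector of measure identifiers.
#' @export
centrality_measures <- function() {
  c("degree", "mnc", "betweenness", "closeness", "katz", "pagerank")
}

#' Compute a node centrality measure
#'
#' Scores are raw (unnormalized): only their relative order matters for
#' ranking, so no normalization is applied. All scores are finite on any
#' graph, including disconnected ones.
#'
#' Details per measure:
#' * `degree`: number of neighbors.
#' * `mnc`: maximum neighborhood component, see [mnc_score()].
#' * `betweenness`: exact shortest-path betweenness (no sampling).
#' * `closeness`: computed per connected component. For a node v in a
#'   component of size \eqn{n_c}, the score is
#'   \eqn{\frac{n_c-1}{n-1}\cdot\frac{n_c-1}{\sum_u d(v,u)}}, the usual
#'   convention that avoids infinite distances on disconnected graphs.
#' * `katz`: \eqn{\sum_{k\ge1} \alpha^k (A^k \mathbf{1})}, evaluated by a
#'   sparse linear solve. The attenuation must satisfy
#'   \eqn{\alpha < 1/\rho(A)} (spectral radius), else the series diverges;
#'   the default is \eqn{0.9/\rho(A)}.
#' * `pagerank`: damped random-walk stationary scores (damping default 0.85);
#'   scores sum to one.
#'
#' @param graph A non-empty igraph object (undirected, simple).
#' @param measure One of [centrality_measures()].
#' @param katz_alpha Katz attenuation factor; default `0.9 / rho(A)`.
#' @param pagerank_damping PageRank damping factor in (0, 1).
#' @return A named numeric vector of class `"centrality_scores"` with one
#'   finite score per node and attribute `measure`.
#' @examples
#' g <- igraph::make_star(5, mode = "undirected")
#' compute_centrality(g, "degree")
#' @export
compute_centrality <- function(graph, measure, katz_alpha = NULL,
                               pagerank_damping = 0.85) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::vcount(graph) == 0) {
    stop("compute_centrality: empty graph")
  }
  measure <- match.arg(measure, centrality_measures())
  nm <- node_names(graph)
  n <- length(nm)
  params <- list()
  scores <- switch(measure,
    degree = as.numeric(igraph::degree(graph)),
    mnc = as.numeric(mnc_all(graph)),
    betweenness = as.numeric(igraph::betweenness(graph, directed = FALSE)),
    closeness = closeness_per_component(graph),
    katz = {
      ks <- katz_scores(graph, katz_alpha)
      params <- list(alpha = attr(ks, "alpha"))
      as.numeric(ks)
    },
    pagerank = {
      params <- list(damping = pagerank_damping)
      as.numeric(igraph::page_rank(graph, damping = pagerank_damping)$vector)
    }
  )
  if (any(!is.finite(scores))) {
    stop("compute_centrality: non-finite ", measure, " score")
  }
  structure(setNames(scores, nm), measure = measure, params = params,
            class = "centrality_scores")
}

#' @export
print.centrality_scores <- function(x, ...) {
  cat("centrality scores (", attr(x, "measure"), ") for ", length(x),
      " nodes\n", sep = "")
  print(head(sort(unclass(x), decreasing = TRUE), 6))
  invisible(x)
}

#' Maximum neighborhood component score of one node
#'
#' The size of the largest connected component of the subgraph induced by the
#' open neighborhood of the node (the node itself excluded). An isolated node
#' scores 0; the center of a star scores 1; any vertex of a triangle scores 2.
#' Always bounded above by the node's degree.
#'
#' @param graph An igraph object.
#' @param node A node id present in `graph`.
#' @return A non-negative integer.
#' @export
mnc_score <- function(graph, node) {
  nm <- node_names(graph)
  i <- match(as.character(node), nm)
  if (is.na(i)) stop("mnc_score: node '", node, "' not in graph")
  nb <- igraph::neighbors(graph, i)
  if (length(nb) == 0) return(0L)
  sub <- igraph::induced_subgraph(graph, nb)
  as.integer(max(igraph::components(sub)$csize))
}

mnc_all <- function(graph) {
  adj <- igraph::as_adj_list(graph)
  vapply(adj, function(nb) {
    if (length(nb) == 0) return(0L)
    if (length(nb) == 1) return(1L)
    sub <- igraph::induced_subgraph(graph, nb)
    as.integer(max(igraph::components(sub)$csize))
  }, integer(1))
}

closeness_per_component <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 1) return(0)
  comp <- igraph::components(graph)
  d <- igraph::distances(graph)
  d[!is.finite(d)] <- 0
  s <- rowSums(d)
  nc <- comp$csize[comp$membership]
  ifelse(nc > 1, (nc - 1) / (n - 1) * (nc - 1) / s, 0)
}

katz_scores <- function(graph, alpha = NULL) {
  n <- igraph::vcount(graph)
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  rho <- spectral_radius(A)
  if (is.null(alpha)) {
    alpha <- if (rho > 0) 0.9 / rho else 0
  }
  if (rho > 0 && alpha >= 1 / rho) {
    stop("katz: attenuation alpha = ", format(alpha),
         " >= 1/spectral radius = ", format(1 / rho),
         "; the Katz series diverges")
  }
  x <- Matrix::solve(Matrix::Diagonal(n) - alpha * A, rep(1, n))
  structure(as.numeric(x) - 1, alpha = alpha)
}

# Largest-magnitude adjacency eigenvalue via shifted power iteration.
# The +I shift makes the top eigenvalue of A + I strictly dominant for any
# undirected graph (including bipartite ones, where -rho is an eigenvalue
# of A), so plain power iteration converges.
spectral_radius <- function(A, tol = 1e-12, maxit = 5000) {
  n <- nrow(A)
  if (n == 0 || length(A@x) == 0) return(0)
  x <- rep(1 / sqrt(n), n)
  lam <- 0
  for (it in seq_len(maxit)) {
    y <- as.numeric(A %*% x) + x
    r <- sum(x * y)               # Rayleigh quotient of A + I
    ny <- sqrt(sum(y * y))
    if (ny == 0) return(0)
    x <- y / ny
    if (abs(r - lam) < tol * max(1, abs(r))) {
      lam <- r
      break
    }
    lam <- r
  }
  max(lam - 1, 0)
}
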