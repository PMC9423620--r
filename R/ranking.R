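#' Rank nodes by descending centrality (classical scheme)
#'
#' The classical seed-selection scheme: nodes sorted by non-increasing score,
#' truncated at the budget. Ties are ordered uniformly at random under the
#' seed so that equal-score nodes are treated without bias while the result
#' stays reproducible.
#'
#' @param scores A `"centrality_scores"` vector (or any named numeric vector).
#' @param budget Number of nodes to select, between 1 and the number of
#'   scored nodes. The maximum budget is the size of the network.
#' @param rng_seed Integer seed for tie-breaking.
#' @return A character vector of node ids of class `"ranked_list"`, in rank
#'   order, with attributes `scheme`, `measure` and `budget`.
#' @export
descending_rank <- function(scores, budget, rng_seed = 1L) {
  check_budget(budget, length(scores))
  n <- length(scores)
  tie <- with_rng(derive_seed(rng_seed, "node-ties"), sample.int(n))
  o <- order(-as.numeric(scores), tie)
  ranked_list(names(scores)[o][seq_len(budget)],
              scheme = "descending",
              measure = attr(scores, "measure"),
              budget = budget)
}

#' Rank nodes community by community (community-aware scheme)
#'
#' Builds a seed list that spreads over the whole network instead of
#' concentrating in one dense region. Communities are first ordered from the
#' largest to the smallest (ties decided at random); nodes are sorted inside
#' their community by descending score (ties again random). The output is then
#' assembled in round-robin passes over the community order: the first pass
#' takes each community's top node, the second pass each community's second
#' node, and so on, skipping exhausted communities, stopping exactly when
#' `budget` nodes have been emitted.
#'
#' Community-order ties and within-community score ties draw from independent
#' seeded streams, so either kind of tie is uniform yet the full ranking is
#' reproducible. The community order is fixed once before emission and not
#' re-sorted as communities empty.
#'
#' @param scores A `"centrality_scores"` vector (or any named numeric vector).
#' @param part A [partition] assigning every scored node to a community.
#' @param budget Number of nodes to select (1 to number of scored nodes).
#' @param rng_seed Integer seed for tie-breaking.
#' @return A `"ranked_list"` character vector as in [descending_rank()], with
#'   `scheme = "community_aware"`.
#' @examples
#' sc <- structure(c(a1 = 9, a2 = 8, a3 = 7, b1 = 5, b2 = 4),
#'                 measure = "degree", class = "centrality_scores")
#' p <- partition(c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B"))
#' community_aware_rank(sc, p, budget = 4)  # a1 b1 a2 b2
#' @export
community_aware_rank <- function(scores, part, budget, rng_seed = 1L) {
  part <- as_partition(part)
  check_budget(budget, length(scores))
  nodes <- names(scores)
  missing <- setdiff(nodes, names(part$assignment))
  if (length(missing)) {
    stop("community_aware_rank: node '", missing[1],
         "' is missing from the partition")
  }
  comm_order <- sort_communities(part, derive_seed(rng_seed, "comm"))
  n <- length(scores)
  tie <- with_rng(derive_seed(rng_seed, "node-ties"), sample.int(n))
  names(tie) <- nodes
  sc <- as.numeric(scores)
  names(sc) <- nodes
  ordered <- lapply(comm_order, function(cid) {
    members <- intersect(part$communities[[cid]], nodes)
    members[order(-sc[members], tie[members])]
  })
  ordered <- ordered[lengths(ordered) > 0]
  pos <- unlist(lapply(ordered, seq_along), use.names = FALSE)
  cidx <- rep(seq_along(ordered), lengths(ordered))
  flat <- unlist(ordered, use.names = FALSE)
  out <- flat[order(pos, cidx)][seq_len(budget)]
  ranked_list(out,
              scheme = "community_aware",
              measure = attr(scores, "measure"),
              budget = budget)
}

ranked_list <- function(nodes, scheme, measure, budget) {
  structure(as.character(nodes), scheme = scheme,
            measure = measure %||% NA_character_,
            budget = as.integer(budget), class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat("ranked list (", attr(x, "scheme"), ", ",
      attr(x, "measure"), "): budget ", attr(x, "budget"), "\n", sep = "")
  print(as.character(unclass(x)))
  invisible(x)
}

check_budget <- function(budget, n) {
  if (length(budget) != 1 || !is.finite(budget) || budget != round(budget) ||
      budget < 1 || budget > n) {
    stop("budget must be an integer in [1, ", n, "], got ", budget)
  }
  invisible(TRUE)
}
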