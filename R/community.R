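#' Node-to-community partition
#'
#' A partition maps every node to exactly one community. Communities are
#' derived from the assignment, are pairwise disjoint by construction, and are
#' all non-empty.
#'
#' @param assignment A character vector of community ids named by node ids
#'   (coercible; factors and numeric ids are converted to strings).
#' @return An object of class `"partition"` with elements `assignment` (named
#'   character vector) and `communities` (named list of node-id vectors).
#' @examples
#' p <- partition(c(a = "1", b = "1", c = "2"))
#' community_sizes(p)
#' @export
partition <- function(assignment) {
  if (length(assignment) == 0) {
    out <- list(assignment = setNames(character(0), character(0)),
                communities = list())
    class(out) <- "partition"
    return(out)
  }
  nodes <- names(assignment)
  if (is.null(nodes) || any(!nzchar(nodes))) {
    stop("partition: 'assignment' must be named by node ids")
  }
  if (anyDuplicated(nodes)) {
    stop("partition: node '", nodes[duplicated(nodes)][1],
         "' assigned more than once")
  }
  comm <- as.character(assignment)
  out <- list(
    assignment = setNames(comm, nodes),
    communities = split(nodes, comm)
  )
  class(out) <- "partition"
  out
}

#' Coerce to a partition
#'
#' Accepts a `partition`, a named vector, a two-column data frame
#' (node, community), or an [igraph::communities] object.
#'
#' @param x Object to coerce.
#' @return A [partition] object.
#' @export
as_partition <- function(x) {
  if (inherits(x, "partition")) return(x)
  if (inherits(x, "communities")) {
    m <- igraph::membership(x)
    return(partition(setNames(as.character(m), names(m))))
  }
  if (is.data.frame(x)) {
    if (ncol(x) < 2) stop("as_partition: need columns (node, community)")
    return(partition(setNames(as.character(x[[2]]), as.character(x[[1]]))))
  }
  if (!is.null(names(x))) {
    return(partition(setNames(as.character(x), names(x))))
  }
  stop("as_partition: cannot coerce object of class ", class(x)[1])
}

#' @export
print.partition <- function(x, ...) {
  sizes <- lengths(x$communities)
  cat("partition: ", length(x$assignment), " nodes in ", length(sizes),
      " communities", sep = "")
  if (length(sizes)) {
    cat(" (sizes ", min(sizes), "-", max(sizes), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Community sizes of a partition
#'
#' @param part A [partition] (or coercible object).
#' @return A named integer vector of community sizes.
#' @export
community_sizes <- function(part) {
  part <- as_partition(part)
  lengths(part$communities)
}

#' Order communities from largest to smallest
#'
#' Returns community ids sorted by decreasing size. Communities of equal size
#' are permuted uniformly at random under the given seed, so the order is
#' reproducible yet unbiased among ties.
#'
#' @param part A [partition] (or coercible object).
#' @param rng_seed Integer seed controlling tie-breaks.
#' @return Character vector of community ids, size-non-increasing.
#' @export
sort_communities <- function(part, rng_seed = 1L) {
  part <- as_partition(part)
  sizes <- lengths(part$communities)
  if (length(sizes) == 0) stop("sort_communities: empty partition")
  ids <- names(sizes)
  tie <- with_rng(derive_seed(rng_seed, "community-order"),
                  sample.int(length(ids)))
  ids[order(-sizes, tie)]
}

#' Mixing parameter of a partitioned graph
#'
#' The mixing parameter of a graph with respect to a partition is the fraction
#' of edges whose endpoints lie in different communities. Low values indicate
#' strong community structure (few inter-community links); high values a weak
#' one.
#'
#' @param graph An igraph object with at least one edge.
#' @param part A [partition] covering every node of `graph`.
#' @return A number in \[0, 1\].
#' @export
mixing_parameter <- function(graph, part) {
  stopifnot(igraph::is_igraph(graph))
  part <- as_partition(part)
  if (igraph::ecount(graph) == 0) {
    stop("mixing_parameter: undefined on a graph with no edges")
  }
  nodes <- node_names(graph)
  missing <- setdiff(nodes, names(part$assignment))
  if (length(missing)) {
    stop("mixing_parameter: node '", missing[1], "' is not in the partition")
  }
  el <- igraph::as_edgelist(graph, names = TRUE)
  mean(part$assignment[el[, 1]] != part$assignment[el[, 2]])
}

#' Classify community-structure strength from the mixing parameter
#'
#' Strength classes: strong for mu <= 0.20, medium for 0.20 < mu < 0.40, and
#' weak for mu >= 0.40.
#'
#' @param mu Mixing parameter(s) in \[0, 1\].
#' @return Character vector with values `"strong"`, `"medium"` or `"weak"`.
#' @export
classify_strength <- function(mu) {
  if (any(!is.finite(mu)) || any(mu < 0) || any(mu > 1)) {
    stop("classify_strength: mu must be in [0, 1]")
  }
  ifelse(mu <= 0.20, "strong", ifelse(mu < 0.40, "medium", "weak"))
}

#' Summarize the community structure of a partitioned graph
#'
#' @param graph An igraph object.
#' @param part A [partition] covering all nodes of `graph`.
#' @return A list with `n_communities`, `min_size`, `max_size`, `mu` and
#'   `strength`.
#' @export
community_report <- function(graph, part) {
  part <- as_partition(part)
  sizes <- lengths(part$communities)
  mu <- mixing_parameter(graph, part)
  list(
    n_communities = length(sizes),
    min_size = min(sizes),
    max_size = max(sizes),
    mu = mu,
    strength = classify_strength(mu)
  )
}
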