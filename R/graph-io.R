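#' Read an undirected graph from a plain-text edge list
#'
#' Each non-comment, non-empty line names one edge by its two endpoint
#' identifiers, separated by whitespace and/or commas. Extra tokens on a line
#' (edge weights, labels) are ignored with a notice. Node identifiers are kept
#' as opaque strings; numeric-looking ids are never renumbered. The result is
#' always a simple undirected graph: self-loops are dropped (with a reported
#' count) and duplicate or reversed-duplicate lines collapse to a single edge.
#'
#' @param path Path to the edge-list file.
#' @param comment_prefix Lines whose first non-blank character starts this
#'   string are skipped (default `"#"`).
#' @return An [igraph::igraph] object, undirected and simple, with character
#'   vertex names.
#' @examples
#' f <- tempfile()
#' writeLines(c("# toy", "a b", "b c", "b a"), f)
#' g <- read_edge_list(f)
#' igraph::ecount(g)  # 2
#' @export
read_edge_list <- function(path, comment_prefix = "#") {
  if (!file.exists(path)) {
    stop("cannot read edge list: file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  keep <- nzchar(trimmed) & !startsWith(trimmed, comment_prefix)
  if (!any(keep)) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  idx <- which(keep)
  tokens <- strsplit(trimmed[keep], "[,[:space:]]+")
  ntok <- lengths(tokens)
  if (any(ntok < 2)) {
    bad <- idx[which(ntok < 2)[1]]
    stop("parse error in ", path, " at line ", bad,
         ": expected at least two tokens")
  }
  if (any(ntok > 2)) {
    message("read_edge_list: ignoring extra tokens on ", sum(ntok > 2),
            " line(s) of ", path)
  }
  ends <- vapply(tokens, function(t) t[1:2], character(2))
  self <- ends[1, ] == ends[2, ]
  if (any(self)) {
    message("read_edge_list: dropped ", sum(self), " self-loop(s)")
  }
  verts <- unique(as.vector(ends))
  el <- t(ends[, !self, drop = FALSE])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  missing <- setdiff(verts, igraph::V(g)$name)
  if (length(missing)) g <- igraph::add_vertices(g, length(missing), name = missing)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a graph as a plain-text edge list
#'
#' One edge per line, endpoint names separated by a single space. Isolated
#' nodes cannot be represented in this format and are silently omitted;
#' round-trips are exact for graphs without isolated nodes.
#'
#' @param graph An igraph object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(igraph::is_igraph(graph))
  el <- igraph::as_edgelist(graph, names = TRUE)
  writeLines(paste(el[, 1], el[, 2]), path)
  invisible(path)
}

#' Read a graph from a GML file
#'
#' Only the topology and node identifiers are used; every other attribute is
#' discarded. Directed or multi-edge inputs are collapsed to a simple
#' undirected graph with a warning, since all ranking and spreading
#' computations in this package are defined on simple undirected graphs.
#'
#' @param path Path to a GML file.
#' @return A simple undirected igraph object with character vertex names.
#' @export
read_gml <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read GML: file not found: ", path)
  }
  g <- igraph::read_graph(path, format = "gml")
  if (igraph::is_directed(g)) {
    warning("read_gml: directed input collapsed to an undirected graph")
    g <- igraph::as_undirected(g, mode = "collapse")
  }
  if (igraph::any_multiple(g) || any(igraph::which_loop(g))) {
    warning("read_gml: multi-edges and/or self-loops removed")
  }
  g <- igraph::simplify(g)
  nm <- igraph::vertex_attr(g, "label") %||%
    igraph::vertex_attr(g, "id") %||%
    seq_len(igraph::vcount(g))
  for (a in igraph::vertex_attr_names(g)) g <- igraph::delete_vertex_attr(g, a)
  for (a in igraph::edge_attr_names(g)) g <- igraph::delete_edge_attr(g, a)
  igraph::set_vertex_attr(g, "name", value = as.character(nm))
}

#' Read a node-to-community partition from a two-column text file
#'
#' Each non-comment line holds a node identifier followed by a community
#' identifier, separated by whitespace and/or commas. A node listed twice with
#' two different communities is an error: overlapping communities are not
#' supported.
#'
#' @param path Path to the partition file.
#' @param comment_prefix Comment-line prefix (default `"#"`).
#' @return A [partition] object.
#' @export
read_partition <- function(path, comment_prefix = "#") {
  if (!file.exists(path)) {
    stop("cannot read partition: file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  keep <- nzchar(trimmed) & !startsWith(trimmed, comment_prefix)
  if (!any(keep)) {
    return(partition(character(0)))
  }
  idx <- which(keep)
  tokens <- strsplit(trimmed[keep], "[,[:space:]]+")
  ntok <- lengths(tokens)
  if (any(ntok < 2)) {
    bad <- idx[which(ntok < 2)[1]]
    stop("parse error in ", path, " at line ", bad,
         ": expected 'node community'")
  }
  node <- vapply(tokens, `[`, character(1), 1L)
  comm <- vapply(tokens, `[`, character(1), 2L)
  dup <- duplicated(node)
  if (any(dup)) {
    conflict <- tapply(comm, node, function(x) length(unique(x)) > 1)
    if (any(conflict)) {
      stop("overlapping assignment: node '", names(conflict)[conflict][1],
           "' listed in more than one community")
    }
    node <- node[!dup]
    comm <- comm[!dup]
  }
  partition(setNames(comm, node))
}

#' Write a partition as a two-column text file
#'
#' @param part A [partition] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(part, path) {
  part <- as_partition(part)
  writeLines(paste(names(part$assignment), part$assignment), path)
  invisible(path)
}
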