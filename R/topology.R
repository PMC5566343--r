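#' p-th order neighborhood of a vertex
#'
#' The set of vertices reachable from `v` by a path of length at most `p`
#' (a BFS ball of radius `p`). The open variant excludes `v` itself, the
#' closed variant includes it.
#'
#' @param graph A PPI network (igraph or edge data frame).
#' @param v A node identifier present in the graph.
#' @param p Neighborhood order (radius), a positive integer.
#' @param closed Include `v` itself?
#' @return A radix-sorted character vector of node identifiers.
#' @examples
#' g <- ppi_network(data.frame(a = c("a", "b", "c"), b = c("b", "c", "d")))
#' p_neighborhood(g, "a", 2)
#' @export
p_neighborhood <- function(graph, v, p, closed = FALSE) {
  g <- as_ppi_network(graph)
  check_vertex(g, v)
  if (!is.numeric(p) || length(p) != 1 || p < 1) {
    rlang::abort("`p` must be a positive integer.")
  }
  ball <- igraph::ego(g, order = p, nodes = v, mindist = if (closed) 0L else 1L)[[1]]
  sort(ball$name, method = "radix")
}

check_vertex <- function(g, v) {
  if (length(v) != 1 || !v %in% igraph::V(g)$name) {
    rlang::abort(sprintf("Vertex '%s' is not in the graph.", paste(v, collapse = ",")))
  }
  invisible(v)
}

#' Induced-subgraph statistics
#'
#' Computes, on the subgraph induced by `s`, the quantities that parameterise
#' the coalition game: the minimum within-subgraph degree, the degree density
#' \eqn{\alpha} (minimum degree over `|s| - 1`), the edge density \eqn{\delta}
#' (edge count over `choose(|s|, 2)`), and the diameter (maximum pairwise
#' shortest-path length; `Inf` when the induced subgraph is disconnected).
#' Within-degrees ignore edges leaving `s`. A singleton has
#' \eqn{\alpha = \delta = 0} and diameter 0.
#'
#' @param graph A PPI network.
#' @param s Non-empty character vector of node identifiers, a subset of the
#'   graph's nodes.
#' @return A list of class `subgraph_stats` with fields `size`,
#'   `min_within_degree`, `edge_count`, `degree_density`, `edge_density`,
#'   `diameter`.
#' @examples
#' g <- ppi_network(data.frame(a = c("a", "b", "c", "d"), b = c("b", "c", "d", "a")))
#' subgraph_stats(g, c("a", "b", "c", "d"))  # 4-cycle
#' @export
subgraph_stats <- function(graph, s) {
  g <- as_ppi_network(graph)
  s <- unique(as.character(s))
  if (length(s) == 0) {
    rlang::abort("`s` must be non-empty.")
  }
  missing <- setdiff(s, igraph::V(g)$name)
  if (length(missing) > 0) {
    rlang::abort(sprintf("Not in graph: %s", paste(missing, collapse = ", ")))
  }
  k <- length(s)
  if (k == 1) {
    out <- list(size = 1L, min_within_degree = 0L, edge_count = 0L,
                degree_density = 0, edge_density = 0, diameter = 0)
    return(structure(out, class = "subgraph_stats"))
  }
  sub <- igraph::induced_subgraph(g, s)
  deg <- igraph::degree(sub)
  m <- igraph::ecount(sub)
  diam <- max(igraph::distances(sub))
  structure(
    list(
      size = k,
      min_within_degree = as.integer(min(deg)),
      edge_count = as.integer(m),
      degree_density = min(deg) / (k - 1),
      edge_density = m / (k * (k - 1) / 2),
      diameter = diam
    ),
    class = "subgraph_stats"
  )
}

#' @export
print.subgraph_stats <- function(x, ...) {
  cat(sprintf(
    "<subgraph_stats> size %d, min degree %d, edges %d, alpha %.3f, delta %.3f, diameter %s\n",
    x$size, x$min_within_degree, x$edge_count, x$degree_density, x$edge_density,
    format(x$diameter)
  ))
  invisible(x)
}

#' Local transitivity (clustering coefficient) of a vertex
#'
#' The fraction of pairs of neighbors of `v` that are themselves connected,
#' i.e. triangles through `v` over triples centered on `v`. Defined as 0 for
#' vertices of degree below 2 (no centered triples).
#'
#' @param graph A PPI network.
#' @param v A node identifier.
#' @return A number in `[0, 1]`.
#' @export
local_transitivity <- function(graph, v) {
  g <- as_ppi_network(graph)
  check_vertex(g, v)
  if (igraph::degree(g, v) < 2) {
    return(0)
  }
  val <- unname(igraph::transitivity(g, type = "local", vids = v))
  if (is.nan(val)) 0 else val
}

#' Rank players for the rule of order
#'
#' Orders the nodes by the geometric mean of degree and local transitivity,
#' descending — the proposer priority ("rule of order") of the sequential
#' game. Ties are broken by degree descending, then node identifier
#' ascending, which makes the ordering fully deterministic.
#'
#' @param graph A PPI network.
#' @return A character vector containing every node exactly once.
#' @examples
#' g <- ppi_network(data.frame(
#'   from = c("a", "a", "b", "a"),
#'   to   = c("b", "c", "c", "d")
#' ))
#' rank_players(g)  # b, c before a; pendant d last
#' @export
rank_players <- function(graph) {
  g <- as_ppi_network(graph)
  if (igraph::vcount(g) == 0) {
    rlang::abort("The graph is empty.")
  }
  nm <- igraph::V(g)$name
  d <- igraph::degree(g)
  tr <- igraph::transitivity(g, type = "local", vids = igraph::V(g))
  tr[is.nan(tr) | is.na(tr)] <- 0
  score <- sqrt(d * tr)
  nm[order(-score, -d, nm, method = "radix")]
}
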