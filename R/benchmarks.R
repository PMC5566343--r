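#' Generate a Girvan-Newman planted-partition benchmark
#'
#' The classic planted 4-partition benchmark: `n_nodes` vertices split into
#' `n_modules` equal modules. Each intra-module pair is linked with
#' probability `p_in = avg_degree * (1 - mu) / (module_size - 1)` and each
#' inter-module pair with `p_out = avg_degree * mu / (n_nodes - module_size)`,
#' so every node has expected total degree `avg_degree` and an expected
#' fraction `mu` of its edges leaving its module (the mixing parameter).
#' For `mu < 0.5` the expected external degree is below the internal one and
#' the planted modules are well defined.
#'
#' @param mu Mixing parameter in `[0, 1]`.
#' @param n_nodes Total vertex count (default 128).
#' @param n_modules Number of planted modules (default 4).
#' @param module_size Vertices per module (default 32); must satisfy
#'   `n_nodes = n_modules * module_size`.
#' @param avg_degree Expected total degree per node (default 16, the
#'   canonical benchmark setting).
#' @param seed Optional integer seed; the generator is bit-reproducible for
#'   a fixed seed.
#' @return A `labeled_network`: a list with `graph` (igraph) and `truth`
#'   (tibble with columns `node`, `module` — the planted partition).
#' @examples
#' net <- generate_gn(mu = 0.1, seed = 1)
#' igraph::vcount(net$graph)
#' table(net$truth$module)
#' @export
generate_gn <- function(mu, n_nodes = 128, n_modules = 4, module_size = 32,
                        avg_degree = 16, seed = NULL) {
  if (!is.numeric(mu) || length(mu) != 1 || mu < 0 || mu > 1) {
    rlang::abort("`mu` must be in [0, 1].")
  }
  if (n_nodes != n_modules * module_size) {
    rlang::abort("Need n_nodes = n_modules * module_size.")
  }
  p_in <- avg_degree * (1 - mu) / (module_size - 1)
  p_out <- if (n_nodes > module_size) avg_degree * mu / (n_nodes - module_size) else 0
  if (p_in < 0 || p_in > 1) {
    rlang::abort(sprintf("Infeasible configuration: p_in = %.4f outside [0, 1].", p_in))
  }
  if (p_out < 0 || p_out > 1) {
    rlang::abort(sprintf("Infeasible configuration: p_out = %.4f outside [0, 1].", p_out))
  }
  width <- nchar(as.character(n_nodes))
  nodes <- sprintf("n%0*d", width, seq_len(n_nodes))
  module <- sprintf("m%02d", rep(seq_len(n_modules), each = module_size))

  draw <- function() {
    pairs <- utils::combn(n_nodes, 2)
    same <- module[pairs[1, ]] == module[pairs[2, ]]
    pr <- ifelse(same, p_in, p_out)
    keep <- stats::runif(ncol(pairs)) < pr
    build_network(nodes[pairs[1, keep]], nodes[pairs[2, keep]], nodes = nodes)
  }
  g <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(
    list(
      graph = g,
      truth = tibble::tibble(node = nodes, module = module)
    ),
    class = "labeled_network"
  )
}

#' @export
print.labeled_network <- function(x, ...) {
  cat(sprintf(
    "<labeled_network> %d nodes, %d edges, %d planted modules\n",
    igraph::vcount(x$graph), igraph::ecount(x$graph),
    length(unique(x$truth$module))
  ))
  invisible(x)
}

#' Generate an Erdos-Renyi G(n, p) null network
#'
#' Every vertex pair is linked independently with probability `edge_prob`.
#' Random graphs of this kind carry no modular structure and serve as the
#' null model: a sound complex-detection method should report little or
#' nothing on them.
#'
#' @param n Number of vertices.
#' @param edge_prob Edge probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return An igraph graph with named vertices (isolates retained).
#' @examples
#' g <- generate_er(10, 0, seed = 1)
#' igraph::ecount(g)
#' @export
generate_er <- function(n, edge_prob, seed = NULL) {
  if (!is.numeric(n) || n < 1) {
    rlang::abort("`n` must be >= 1.")
  }
  if (!is.numeric(edge_prob) || edge_prob < 0 || edge_prob > 1) {
    rlang::abort("`edge_prob` must be in [0, 1].")
  }
  width <- nchar(as.character(n))
  nodes <- sprintf("n%0*d", width, seq_len(n))
  draw <- function() {
    if (n == 1) {
      return(build_network(character(), character(), nodes = nodes))
    }
    pairs <- utils::combn(n, 2)
    keep <- stats::runif(ncol(pairs)) < edge_prob
    build_network(nodes[pairs[1, keep]], nodes[pairs[2, keep]], nodes = nodes)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Perturb a network by random endpoint rewiring
#'
#' Independently for each edge endpoint, with probability `rho` the endpoint
#' is replaced by a vertex drawn uniformly from the vertex set. Self-loops
#' and duplicate edges created by rewiring are discarded (the simple-graph
#' invariant), so the edge count never increases. The input graph is left
#' untouched; `rho = 0` returns a graph identical to the input.
#'
#' @param graph A PPI network.
#' @param rho Rewiring probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A new igraph graph on the same vertex set.
#' @export
rewire_edges <- function(graph, rho, seed = NULL) {
  g <- as_ppi_network(graph)
  if (!is.numeric(rho) || rho < 0 || rho > 1) {
    rlang::abort("`rho` must be in [0, 1].")
  }
  nm <- igraph::V(g)$name
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0 || rho == 0) {
    return(build_network(el[, 1], el[, 2], nodes = nm))
  }
  draw <- function() {
    ends <- c(el[, 1], el[, 2])
    hit <- stats::runif(length(ends)) < rho
    if (any(hit)) {
      ends[hit] <- nm[sample.int(length(nm), sum(hit), replace = TRUE)]
    }
    m <- nrow(el)
    build_network(ends[seq_len(m)], ends[m + seq_len(m)], nodes = nm)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
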