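#' Build a PPI network from an edge table
#'
#' Constructs an undirected simple graph over opaque, case-sensitive string
#' node identifiers. Self-loops are dropped and duplicate edges collapsed, so
#' the result always satisfies the simple-graph invariant the coalition game
#' assumes. Isolated nodes may be kept by listing them in `nodes`.
#'
#' @param edges A data frame whose first two columns are the edge endpoints
#'   (coerced to character), or `NULL` for an edgeless network.
#' @param nodes Optional character vector of node identifiers to include even
#'   when they touch no edge.
#' @param quiet If `FALSE`, report the number of self-loops dropped.
#' @return An [igraph][igraph::igraph-package] graph with a `name` vertex
#'   attribute; vertices are stored in radix-sorted name order so that the
#'   same edge set always yields the identical object.
#' @examples
#' g <- ppi_network(data.frame(a = c("p1", "p2"), b = c("p2", "p3")))
#' igraph::vcount(g)
#' @export
ppi_network <- function(edges = NULL, nodes = NULL, quiet = TRUE) {
  if (is.null(edges)) {
    return(build_network(character(), character(), nodes = nodes, quiet = quiet))
  }
  if (!is.data.frame(edges) || ncol(edges) < 2) {
    rlang::abort("`edges` must be a data frame with at least two columns.")
  }
  build_network(as.character(edges[[1]]), as.character(edges[[2]]),
                nodes = nodes, quiet = quiet)
}

# Shared constructor: canonicalise endpoints, drop loops/duplicates, sort names.
build_network <- function(from, to, nodes = NULL, quiet = TRUE) {
  # a vertex named only by a self-loop line is kept as an isolated node
  all_nodes <- sort(unique(c(nodes, from, to)), method = "radix")
  keep <- from != to
  n_loops <- sum(!keep)
  if (n_loops > 0 && !quiet) {
    rlang::inform(sprintf("Dropped %d self-loop(s).", n_loops))
  }
  from <- from[keep]
  to <- to[keep]
  a <- pmin(from, to)
  b <- pmax(from, to)
  dup <- duplicated(paste(a, b, sep = "\t"))
  a <- a[!dup]
  b <- b[!dup]
  g <- igraph::make_empty_graph(n = length(all_nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = all_nodes)
  if (length(a) > 0) {
    g <- igraph::add_edges(g, rbind(match(a, all_nodes), match(b, all_nodes)))
  }
  g
}

#' Coerce an object to a PPI network
#'
#' Accepts an igraph graph (made undirected and simple if needed, vertex
#' names required or synthesised from indices) or an edge-list data frame.
#'
#' @param x An igraph graph or a data frame of edges.
#' @return An undirected simple igraph graph with named vertices.
#' @keywords internal
#' @export
as_ppi_network <- function(x) {
  if (igraph::is_igraph(x)) {
    if (igraph::is_directed(x)) {
      x <- igraph::as_undirected(x, mode = "collapse")
    }
    if (!igraph::is_simple(x)) {
      x <- igraph::simplify(x, remove.multiple = TRUE, remove.loops = TRUE)
    }
    if (is.null(igraph::V(x)$name)) {
      igraph::V(x)$name <- as.character(seq_len(igraph::vcount(x)))
    }
    return(x)
  }
  if (is.data.frame(x)) {
    return(ppi_network(x))
  }
  rlang::abort("Cannot interpret `x` as a PPI network; supply an igraph graph or an edge data frame.")
}

#' Read a PPI network from an edge-list file
#'
#' Reads a two-column whitespace/tab-separated edge list, or a SIF file
#' (`nodeA interaction nodeB`, middle token ignored). Lines starting with `#`
#' and blank lines are skipped. Node identifiers are taken verbatim
#' (case-sensitive). Self-loops are dropped (with a message giving the count)
#' and duplicate edges are collapsed.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (endpoints in columns 1-2) or `"sif"` (endpoints in
#'   columns 1 and 3).
#' @return An undirected simple igraph graph with named vertices.
#' @examples
#' f <- tempfile()
#' writeLines(c("p1\tp2", "p2\tp3"), f)
#' g <- read_edge_list(f)
#' igraph::ecount(g)
#' @export
read_edge_list <- function(path, dialect = c("tsv", "sif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: '%s'", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0) {
    rlang::abort(sprintf("No edge records in '%s' (empty file?).", path))
  }
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  need <- if (dialect == "sif") 3L else 2L
  bad <- which(lengths(toks) < need)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "Malformed line %d in '%s': expected at least %d whitespace-separated fields.",
      keep[bad[1]], path, need
    ))
  }
  from <- vapply(toks, `[[`, character(1), 1L)
  to <- vapply(toks, `[[`, character(1), if (dialect == "sif") 3L else 2L)
  build_network(from, to, quiet = FALSE)
}

#' Read a complex-membership file
#'
#' One complex per line, members separated by whitespace or tabs. Blank lines
#' and `#` comment lines are skipped; duplicate members within a line are
#' collapsed. This is the format used for reference (gold-standard) complex
#' sets and for the output of most complex-detection tools.
#'
#' @param path Path to the file.
#' @return A `complex_set`: a list of character vectors of member identifiers,
#'   in file order, with a `name` attribute set to the file name.
#' @examples
#' f <- tempfile()
#' writeLines(c("p1 p2 p3", "p4 p5"), f)
#' lengths(read_complexes(f))
#' @export
read_complexes <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: '%s'", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0) {
    rlang::abort(sprintf("No complexes in '%s' (empty file?).", path))
  }
  sets <- lapply(strsplit(trimws(lines[keep]), "\\s+"), unique)
  complex_set(sets, name = basename(path))
}

#' Construct a complex set
#'
#' @param x A list of character vectors (complex member identifiers). Sets may
#'   overlap; empty sets are an error.
#' @param name Free-text label.
#' @return A `complex_set` object (list of character vectors).
#' @export
complex_set <- function(x, name = "") {
  if (!is.list(x)) {
    rlang::abort("`x` must be a list of character vectors.")
  }
  x <- lapply(x, function(s) unique(as.character(s)))
  if (any(lengths(x) == 0)) {
    rlang::abort("Complexes must be non-empty.")
  }
  structure(x, class = "complex_set", name = name)
}

#' @export
print.complex_set <- function(x, ...) {
  nm <- attr(x, "name")
  cat(sprintf(
    "<complex_set%s> %d complex(es), sizes %s\n",
    if (nzchar(nm)) paste0(" ", nm) else "", length(x),
    paste(range(lengths(x)), collapse = "-")
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a complex set into a long membership table
#'
#' @param x A `complex_set`.
#' @param ... Unused.
#' @return A tibble with columns `complex` (1-based index) and `member`.
#' @export
tidy.complex_set <- function(x, ...) {
  tibble::tibble(
    complex = rep(seq_along(x), lengths(x)),
    member = unlist(x, use.names = FALSE)
  )
}

#' Write detected complexes to a membership file
#'
#' Writes one coalition per line with members tab-separated in lexicographic
#' order, coalitions in detection order. Residual singletons are appended one
#' per line when `include_singletons` is set.
#'
#' @param cover A [nash_pdc()] result (`pdc_cover`), a `complex_set`, or a
#'   plain list of character vectors.
#' @param path Output file path.
#' @param include_singletons Append residual vertices as singleton lines
#'   (only meaningful for `pdc_cover` input).
#' @return Invisibly, `path`.
#' @export
write_cover_set <- function(cover, path, include_singletons = FALSE) {
  if (inherits(cover, "pdc_cover")) {
    sets <- lapply(cover$coalitions, `[[`, "members")
    residual <- cover$residual
  } else if (is.list(cover)) {
    sets <- lapply(cover, as.character)
    residual <- character()
  } else {
    rlang::abort("`cover` must be a pdc_cover, a complex_set, or a list of character vectors.")
  }
  lines <- vapply(
    sets,
    function(s) paste(sort(s, method = "radix"), collapse = "\t"),
    character(1)
  )
  if (include_singletons && length(residual) > 0) {
    lines <- c(lines, sort(residual, method = "radix"))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# Canonical edge key set, used for graph equality in tests and rewiring.
edge_key_set <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0) return(character())
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\t"),
       method = "radix")
}
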