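# Independent brute-force oracles, deliberately written along different
# routes than the package internals.

# Local transitivity by exhaustive neighbor-pair enumeration.
oracle_transitivity <- function(g, v) {
  nbrs <- names(igraph::neighbors(g, v))
  if (length(nbrs) < 2) return(0)
  pairs <- utils::combn(nbrs, 2)
  closed <- sum(vapply(
    seq_len(ncol(pairs)),
    function(i) igraph::are_adjacent(g, pairs[1, i], pairs[2, i]),
    logical(1)
  ))
  closed / ncol(pairs)
}

# Feasibility of a vertex set straight from the definitions, via igraph.
oracle_feasible <- function(g, s, config) {
  k <- length(s)
  if (k < config$min_size) return(FALSE)
  sub <- igraph::induced_subgraph(g, s)
  deg <- igraph::degree(sub)
  if (min(deg) / (k - 1) < config$lambda) return(FALSE)
  if (igraph::ecount(sub) / (k * (k - 1) / 2) < config$gamma) return(FALSE)
  d <- max(igraph::distances(sub))
  is.finite(d) && d <= config$p
}

# All feasible subsets of `nodes` by exhaustive enumeration.
oracle_feasible_subsets <- function(g, nodes, config) {
  found <- list()
  n <- length(nodes)
  if (n < config$min_size) return(found)
  for (k in seq(config$min_size, n)) {
    combos <- utils::combn(nodes, k, simplify = FALSE)
    for (s in combos) {
      if (oracle_feasible(g, s, config)) found[[length(found) + 1]] <- s
    }
  }
  found
}

# NMI through the entropy identity 2 * (H(a) + H(b) - H(a,b)) / (H(a) + H(b)),
# a different route than the direct mutual-information sum.
oracle_nmi <- function(ma, mb) {
  mb <- mb[names(ma)]
  n <- length(ma)
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  ha <- ent(as.vector(table(ma)) / n)
  hb <- ent(as.vector(table(mb)) / n)
  hab <- ent(as.vector(table(paste(ma, mb, sep = "\r"))) / n)
  if (ha + hb == 0) return(1)
  2 * (ha + hb - hab) / (ha + hb)
}

# Random partition of `nodes` into at most k classes (every class non-empty
# not required for NMI, empty classes simply never occur in the table).
random_partition <- function(nodes, k) {
  data.frame(node = nodes, cls = sample.int(k, length(nodes), replace = TRUE))
}
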