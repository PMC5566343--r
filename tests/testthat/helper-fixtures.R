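# Build an undirected simple graph from pairs: g_edges("a","b", "b","c").
g_edges <- function(..., isolates = NULL) {
  v <- c(...)
  stopifnot(length(v) %% 2 == 0)
  idx <- seq(1, length(v), by = 2)
  ppi_network(data.frame(from = v[idx], to = v[idx + 1]), nodes = isolates)
}

# Complete graph on the given node names.
g_complete <- function(nodes) {
  pr <- t(utils::combn(nodes, 2))
  ppi_network(data.frame(from = pr[, 1], to = pr[, 2]))
}

# Edges of a K_k minus a perfect matching over consecutive pairs (1-2, 3-4, ...).
block_edges <- function(ids) {
  pr <- t(utils::combn(ids, 2))
  matching <- matrix(ids, ncol = 2, byrow = TRUE)
  keep <- !(paste(pr[, 1], pr[, 2]) %in% paste(matching[, 1], matching[, 2]))
  pr[keep, , drop = FALSE]
}

# Two 6-vertex blocks (K6 minus a perfect matching: 12 edges, alpha = delta =
# 0.8, diameter 2 each) joined by a single bridge edge p06-p07.
bridged_blocks <- function() {
  b1 <- block_edges(sprintf("p%02d", 1:6))
  b2 <- block_edges(sprintf("p%02d", 7:12))
  edges <- rbind(b1, b2, c("p06", "p07"))
  list(
    graph = ppi_network(as.data.frame(edges)),
    block1 = sprintf("p%02d", 1:6),
    block2 = sprintf("p%02d", 7:12)
  )
}

# Canonical representation for graph equality.
edge_keys <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0) return(character())
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|"))
}

expect_same_graph <- function(g1, g2) {
  expect_setequal(igraph::V(g1)$name, igraph::V(g2)$name)
  expect_identical(edge_keys(g1), edge_keys(g2))
}

# Membership sets of a cover, order-independent comparison helper.
cover_sets <- function(cover) {
  lapply(cover$coalitions, `[[`, "members")
}
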