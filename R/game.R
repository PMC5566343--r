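#' Game configuration for the partial dense vertex cover game
#'
#' Holds the tunable constraints of a coalition (candidate complex): the
#' degree-density floor `lambda`, the edge-density floor `gamma`, the
#' diameter bound `p`, and the minimum coalition size. The constraint
#' `0 < lambda <= gamma <= 1` is enforced. `seed` is recorded for
#' provenance; the default engine is fully deterministic and does not
#' consume it.
#'
#' @param lambda Degree-density floor \eqn{\lambda} in `(0, 1]`: every
#'   coalition member must have within-coalition degree at least
#'   `lambda * (size - 1)`.
#' @param gamma Edge-density floor \eqn{\gamma} in `(0, 1]`, with
#'   `lambda <= gamma`.
#' @param p Diameter bound (and neighborhood order used for proposals), a
#'   positive integer.
#' @param min_size Minimum coalition cardinality, an integer `>= 2`.
#' @param seed Optional integer seed, recorded in the object.
#' @return A `pdc_config` object.
#' @examples
#' pdc_config()
#' pdc_config(lambda = 0.001, gamma = 0.001)  # sparse-complex mode
#' @export
pdc_config <- function(lambda = 0.6, gamma = 0.65, p = 2, min_size = 3,
                       seed = NULL) {
  if (!is.numeric(lambda) || !is.numeric(gamma) ||
      lambda <= 0 || lambda > gamma || gamma > 1) {
    rlang::abort("Need 0 < lambda <= gamma <= 1.")
  }
  if (!is.numeric(p) || length(p) != 1 || p < 1 || p != floor(p)) {
    rlang::abort("`p` must be a positive integer.")
  }
  if (!is.numeric(min_size) || length(min_size) != 1 || min_size < 2 ||
      min_size != floor(min_size)) {
    rlang::abort("`min_size` must be an integer >= 2.")
  }
  structure(
    list(lambda = lambda, gamma = gamma, p = as.integer(p),
         min_size = as.integer(min_size),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "pdc_config"
  )
}

#' @export
print.pdc_config <- function(x, ...) {
  cat(sprintf(
    "<pdc_config> lambda = %g, gamma = %g, p = %d, min_size = %d%s\n",
    x$lambda, x$gamma, x$p, x$min_size,
    if (is.null(x$seed)) "" else sprintf(", seed = %d", x$seed)
  ))
  invisible(x)
}

# ---- dense-matrix feasibility kernel ---------------------------------------
# A: symmetric 0/1 adjacency of the candidate set, zero diagonal.
# A set is feasible when alpha >= lambda, delta >= gamma and its induced
# diameter is at most p (which implies connectedness). Cheap checks first;
# the diameter test runs only when both density floors already hold.

feasible_dense <- function(A, config, require_size = TRUE) {
  k <- nrow(A)
  if (require_size && k < config$min_size) return(FALSE)
  if (k < 2) return(FALSE)
  deg <- colSums(A)
  if (min(deg) / (k - 1) < config$lambda) return(FALSE)
  if (sum(deg) / (k * (k - 1)) < config$gamma) return(FALSE)
  diameter_at_most(A, config$p)
}

# (A + I)^p has no zero entry  <=>  every pair is joined by a path of
# length <= p  <=>  connected with diameter <= p.
diameter_at_most <- function(A, p) {
  B <- A
  diag(B) <- 1
  M <- B
  i <- 1L
  while (i < p && any(M == 0)) {
    M <- (M %*% B) > 0
    storage.mode(M) <- "double"
    i <- i + 1L
  }
  all(M > 0)
}

# ---- best-response refinement ----------------------------------------------
# Works in full-graph vertex indices against the sparse adjacency `Adj`.
# Returns the refined member indices, or NULL on failure.
refine_core <- function(Adj, nm, cand_idx, proposer_idx, config, active_idx) {
  k <- length(cand_idx)
  if (k < config$min_size) return(NULL)

  A <- as.matrix(Adj[cand_idx, cand_idx, drop = FALSE])
  storage.mode(A) <- "double"
  deg <- colSums(A)
  m <- sum(deg) / 2
  present <- rep(TRUE, k)
  ppos <- match(proposer_idx, cand_idx)

  feas_now <- function() {
    kk <- sum(present)
    if (kk < 2) return(FALSE)
    dsub <- deg[present]
    if (min(dsub) / (kk - 1) < config$lambda) return(FALSE)
    if ((2 * m) / (kk * (kk - 1)) < config$gamma) return(FALSE)
    diameter_at_most(A[present, present, drop = FALSE], config$p)
  }

  # (1) prune: drop the weakest-connected non-proposer while infeasible
  repeat {
    if (feas_now()) {
      ok <- TRUE
      break
    }
    if (sum(present) <= config$min_size) {
      ok <- FALSE
      break
    }
    idx <- which(present)
    idx <- idx[idx != ppos]
    dsub <- deg[idx]
    tied <- idx[dsub == min(dsub)]
    # ties: remove the lexicographically largest identifier first
    rm_pos <- tied[order(nm[cand_idx[tied]], method = "radix", decreasing = TRUE)][1]
    present[rm_pos] <- FALSE
    m <- m - deg[rm_pos]
    deg <- deg - A[, rm_pos]
  }
  if (!ok) return(NULL)

  # (3) grow to local maximality among active players
  mem <- cand_idx[present]
  repeat {
    outside <- setdiff(active_idx, mem)
    if (length(outside) == 0) break
    links <- Matrix::rowSums(Adj[outside, mem, drop = FALSE])
    outside <- outside[links > 0]
    links <- links[links > 0]
    if (length(outside) == 0) break
    ord <- order(-links, nm[outside], method = "radix")
    added <- FALSE
    for (w in outside[ord]) {
      trial <- c(mem, w)
      At <- as.matrix(Adj[trial, trial, drop = FALSE])
      storage.mode(At) <- "double"
      if (feasible_dense(At, config)) {
        mem <- c(mem, w)
        added <- TRUE
        break
      }
    }
    if (!added) break
  }
  sort(mem)
}

new_coalition <- function(g, members, proposer) {
  structure(
    list(
      members = sort(members, method = "radix"),
      proposer = proposer,
      stats = subgraph_stats(g, members)
    ),
    class = "pdc_coalition"
  )
}

#' @export
print.pdc_coalition <- function(x, ...) {
  cat(sprintf(
    "<pdc_coalition> %d members (proposer %s), alpha %.3f, delta %.3f, diameter %s\n",
    length(x$members), x$proposer, x$stats$degree_density,
    x$stats$edge_density, format(x$stats$diameter)
  ))
  invisible(x)
}

#' Propose a coalition: the proposer's closed p-ball among active players
#'
#' The opening move of a game round: player `proposer` invites its closed
#' `p`-th order neighborhood, restricted to players still in the game.
#'
#' @param graph A PPI network.
#' @param proposer Node identifier of the proposing player.
#' @param config A [pdc_config()].
#' @param active Character vector of active (unassigned) players; defaults to
#'   all nodes. The proposer must be active.
#' @return A radix-sorted character vector: the candidate coalition.
#' @export
propose_coalition <- function(graph, proposer, config = pdc_config(),
                              active = NULL) {
  g <- as_ppi_network(graph)
  check_vertex(g, proposer)
  if (is.null(active)) active <- igraph::V(g)$name
  if (!proposer %in% active) {
    rlang::abort(sprintf("Proposer '%s' is already assigned to a coalition.", proposer))
  }
  ball <- p_neighborhood(g, proposer, config$p, closed = TRUE)
  sort(intersect(ball, active), method = "radix")
}

#' Refine a candidate coalition by best-response dynamics
#'
#' Operationalises the accept/reject round of the game: members whose
#' presence blocks feasibility reject the invitation. Concretely the
#' candidate is (1) pruned — while the degree-density, edge-density or
#' diameter constraint is violated and more than `min_size` members remain,
#' the non-proposer member with the smallest within-coalition degree leaves
#' (ties: lexicographically larger identifier first); a disconnected
#' candidate has infinite diameter and is pruned by the same rule; (2)
#' checked — if the constraints still fail, the proposal collapses and
#' `NULL` is returned; (3) grown to local maximality — the active
#' non-member with the most links into the coalition whose addition
#' preserves all constraints joins (ties: lexicographically smaller
#' identifier first), repeatedly, until no such vertex exists.
#'
#' @inheritParams propose_coalition
#' @param candidate Character vector of active players containing `proposer`.
#' @return A `pdc_coalition` (members, proposer, stats), or `NULL` when no
#'   feasible coalition survives.
#' @export
refine_coalition <- function(graph, candidate, proposer,
                             config = pdc_config(), active = NULL) {
  g <- as_ppi_network(graph)
  nm <- igraph::V(g)$name
  candidate <- unique(as.character(candidate))
  if (!all(candidate %in% nm)) {
    rlang::abort("`candidate` contains vertices not in the graph.")
  }
  if (!proposer %in% candidate) {
    rlang::abort("`proposer` must be a member of `candidate`.")
  }
  if (is.null(active)) active <- nm
  if (!all(candidate %in% active)) {
    rlang::abort("All candidate members must be active players.")
  }
  Adj <- g[]
  mem <- refine_core(Adj, nm,
                     cand_idx = match(candidate, nm),
                     proposer_idx = match(proposer, nm),
                     config = config,
                     active_idx = match(intersect(active, nm), nm))
  if (is.null(mem)) return(NULL)
  new_coalition(g, nm[mem], proposer)
}

#' Detect protein complexes by playing the sequential coalition game
#'
#' Plays the sequential non-cooperative partial dense vertex cover game.
#' The rule of order is computed once on the full graph by [rank_players()].
#' In rank order, each still-active player proposes its closed p-ball among
#' active players; the proposal is refined by [refine_coalition()]'s
#' best-response dynamics. On success the stable coalition's members quit
#' the game; on failure the proposer is exhausted (it never proposes again
#' but remains joinable). The game ends when every active player has had
#' its proposal; leftover players form the residual (singleton clusters).
#' The result partitions the vertex set into coalitions plus residual and
#' always passes [verify_cover_set()] properties (a)-(f).
#'
#' @param graph A PPI network (igraph graph or edge-list data frame).
#' @param config A [pdc_config()].
#' @return A `pdc_cover` object with elements `coalitions` (list of
#'   `pdc_coalition` in detection order), `residual` (character vector),
#'   `config`, and `n_nodes`. Supports [tidy()], [glance()],
#'   [cover_partition()], [cover_complexes()] and `autoplot()`.
#' @examples
#' g <- ppi_network(data.frame(
#'   from = c("a", "a", "a", "b", "b", "c"),
#'   to   = c("b", "c", "d", "c", "d", "d")
#' ))
#' nash_pdc(g)
#' @export
nash_pdc <- function(graph, config = pdc_config()) {
  g <- as_ppi_network(graph)
  n <- igraph::vcount(g)
  if (n == 0) {
    rlang::abort("The graph is empty.")
  }
  nm <- igraph::V(g)$name
  Adj <- g[]
  ranked_idx <- match(rank_players(g), nm)
  active <- rep(TRUE, n)
  coalitions <- list()
  for (v in ranked_idx) {
    if (!active[v]) next
    ball <- as.integer(igraph::ego(g, order = config$p, nodes = v, mindist = 0L)[[1]])
    cand <- ball[active[ball]]
    mem <- refine_core(Adj, nm, cand, v, config, active_idx = which(active))
    if (is.null(mem)) next  # proposer exhausted; stays joinable
    coalitions[[length(coalitions) + 1L]] <- new_coalition(g, nm[mem], nm[v])
    active[mem] <- FALSE
  }
  structure(
    list(
      coalitions = coalitions,
      residual = sort(nm[active], method = "radix"),
      config = config,
      n_nodes = n
    ),
    class = "pdc_cover"
  )
}

#' @export
print.pdc_cover <- function(x, ...) {
  sizes <- vapply(x$coalitions, function(co) length(co$members), integer(1))
  cat(sprintf(
    "<pdc_cover> %d coalition(s) covering %d of %d nodes; %d residual singleton(s)\n",
    length(x$coalitions), sum(sizes), x$n_nodes, length(x$residual)
  ))
  cat(sprintf("  lambda = %g, gamma = %g, p = %d, min_size = %d\n",
              x$config$lambda, x$config$gamma, x$config$p, x$config$min_size))
  if (length(sizes) > 0) {
    cat(sprintf("  coalition sizes: %s\n", paste(sizes, collapse = ", ")))
  }
  invisible(x)
}

#' Verify a cover against the partial dense vertex cover definition
#'
#' Checks the defining properties of a partial dense vertex cover:
#' (a) coalitions are non-empty, (b) pairwise disjoint, (c) contained in the
#' vertex set, (d) each has diameter at most `p`, (e) each meets the density
#' floors `alpha >= lambda` and `delta >= gamma` (and the configured minimum
#' size), (f) each is locally maximal — no residual vertex can join it
#' without breaking (d)-(e) — and optionally (g) the residual contains no
#' feasible subset of size at least `min_size`, verified by exhaustive
#' subset enumeration (only when `exhaustive_residual_check` is set and the
#' residual has at most `residual_bound` vertices).
#'
#' @param graph A PPI network.
#' @param cover A `pdc_cover`, or a list of character vectors (coalition
#'   member sets) in which case the residual is the complement of their
#'   union.
#' @param config A [pdc_config()]; defaults to the cover's own config.
#' @param exhaustive_residual_check Run the exhaustive residual check (g)?
#' @param residual_bound Size cap on the residual for check (g).
#' @return A list with `pass` (logical) and `violations`, a tibble with
#'   columns `property` (letter a-g, or "size") and `detail`.
#' @export
verify_cover_set <- function(graph, cover, config = NULL,
                             exhaustive_residual_check = FALSE,
                             residual_bound = 15) {
  g <- as_ppi_network(graph)
  nm <- igraph::V(g)$name
  if (inherits(cover, "pdc_cover")) {
    sets <- lapply(cover$coalitions, `[[`, "members")
    if (is.null(config)) config <- cover$config
  } else if (is.list(cover)) {
    sets <- lapply(cover, as.character)
  } else {
    rlang::abort("`cover` must be a pdc_cover or a list of member sets.")
  }
  if (is.null(config)) config <- pdc_config()

  viol <- list()
  add_viol <- function(property, detail) {
    viol[[length(viol) + 1L]] <<- tibble::tibble(property = property, detail = detail)
  }

  # (a) non-empty subsets of V; (c) union within V
  if (any(lengths(sets) == 0)) {
    add_viol("a", "empty coalition present")
  }
  stray <- setdiff(unlist(sets), nm)
  if (length(stray) > 0) {
    add_viol("c", sprintf("members outside the vertex set: %s",
                          paste(utils::head(stray, 5), collapse = ", ")))
  }
  sets <- lapply(sets, function(s) intersect(s, nm))
  sets <- sets[lengths(sets) > 0]

  # (b) pairwise disjoint
  all_members <- unlist(sets)
  dup <- unique(all_members[duplicated(all_members)])
  if (length(dup) > 0) {
    add_viol("b", sprintf("vertices in more than one coalition: %s",
                          paste(utils::head(dup, 5), collapse = ", ")))
  }

  residual <- setdiff(nm, all_members)

  # (d), (e) and minimum size, per coalition
  for (i in seq_along(sets)) {
    st <- subgraph_stats(g, sets[[i]])
    if (st$size < config$min_size) {
      add_viol("size", sprintf("coalition %d has %d < %d members",
                               i, st$size, config$min_size))
    }
    if (!is.finite(st$diameter) || st$diameter > config$p) {
      add_viol("d", sprintf("coalition %d has diameter %s > %d",
                            i, format(st$diameter), config$p))
    }
    if (st$degree_density < config$lambda || st$edge_density < config$gamma) {
      add_viol("e", sprintf(
        "coalition %d has alpha = %.4f, delta = %.4f (floors %g, %g)",
        i, st$degree_density, st$edge_density, config$lambda, config$gamma
      ))
    }
  }

  # (f) local maximality with respect to residual vertices
  Adj <- g[]
  for (i in seq_along(sets)) {
    mem_idx <- match(sets[[i]], nm)
    if (length(residual) == 0) break
    res_idx <- match(residual, nm)
    links <- Matrix::rowSums(Adj[res_idx, mem_idx, drop = FALSE])
    for (w in res_idx[links > 0]) {
      trial <- c(mem_idx, w)
      At <- as.matrix(Adj[trial, trial, drop = FALSE])
      storage.mode(At) <- "double"
      if (feasible_dense(At, config, require_size = FALSE)) {
        add_viol("f", sprintf("vertex %s can join coalition %d preserving the constraints",
                              nm[w], i))
      }
    }
  }

  # (g) residual contains no feasible subset (exhaustive, small residuals only)
  if (exhaustive_residual_check && length(residual) >= config$min_size &&
      length(residual) <= residual_bound) {
    res_idx <- match(residual, nm)
    Ar <- as.matrix(Adj[res_idx, res_idx, drop = FALSE])
    storage.mode(Ar) <- "double"
    found <- find_feasible_subset(Ar, config)
    if (!is.null(found)) {
      add_viol("g", sprintf("residual contains the feasible subset {%s}",
                            paste(residual[found], collapse = ", ")))
    }
  }

  violations <- if (length(viol) == 0) {
    tibble::tibble(property = character(), detail = character())
  } else {
    dplyr::bind_rows(viol)
  }
  list(pass = nrow(violations) == 0, violations = violations)
}

# Exhaustive search for a feasible subset of the vertex set underlying the
# dense adjacency A. Returns indices of the first feasible subset found, or
# NULL. Used by the verifier's residual check (g).
find_feasible_subset <- function(A, config) {
  n <- nrow(A)
  if (n < config$min_size) return(NULL)
  for (k in seq(config$min_size, n)) {
    combos <- utils::combn(n, k)
    for (j in seq_len(ncol(combos))) {
      s <- combos[, j]
      if (feasible_dense(A[s, s, drop = FALSE], config)) {
        return(s)
      }
    }
  }
  NULL
}
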