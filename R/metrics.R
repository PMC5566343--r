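# ---- partition / complex-set coercion --------------------------------------

# Accepts: a pdc_cover (residual singletons become singleton classes), a
# two-column data frame (node, class), or a named/unnamed list of disjoint
# member sets. Returns a named character vector: names = nodes, values =
# class labels.
as_membership <- function(x, arg = "partition") {
  if (inherits(x, "pdc_cover")) {
    x <- cover_partition(x)
  }
  if (is.data.frame(x)) {
    if (ncol(x) < 2) {
      rlang::abort(sprintf("`%s` must have at least two columns (node, class).", arg))
    }
    nodes <- as.character(x[[1]])
    cls <- as.character(x[[2]])
  } else if (is.list(x)) {
    nodes <- as.character(unlist(x, use.names = FALSE))
    cls <- rep(
      if (is.null(names(x))) as.character(seq_along(x)) else names(x),
      lengths(x)
    )
  } else {
    rlang::abort(sprintf("Cannot interpret `%s` as a partition.", arg))
  }
  if (anyDuplicated(nodes)) {
    rlang::abort(sprintf("`%s` is not a partition: some nodes appear in more than one class.", arg))
  }
  stats::setNames(cls, nodes)
}

# Accepts a complex_set, a plain list of member sets, or a pdc_cover (whose
# predicted complexes exclude residual singletons by default).
as_complex_list <- function(x, arg = "complexes") {
  if (inherits(x, "pdc_cover")) {
    x <- cover_complexes(x)
  }
  if (!is.list(x)) {
    rlang::abort(sprintf("`%s` must be a complex_set or a list of member sets.", arg))
  }
  sets <- lapply(x, function(s) unique(as.character(s)))
  if (length(sets) == 0 || any(lengths(sets) == 0)) {
    rlang::abort(sprintf("`%s` must contain at least one non-empty complex.", arg))
  }
  sets
}

#' Full partition induced by a cover
#'
#' Every node is either in a coalition or a singleton cluster, so a cover
#' induces a partition of the vertex set: coalitions become classes
#' `C1, C2, ...` in detection order and each residual vertex becomes its own
#' singleton class. This is the partition used when scoring a detection
#' against planted ground truth with [nmi()].
#'
#' @param cover A `pdc_cover` from [nash_pdc()].
#' @return A tibble with columns `node` and `cluster`.
#' @export
cover_partition <- function(cover) {
  if (!inherits(cover, "pdc_cover")) {
    rlang::abort("`cover` must be a pdc_cover.")
  }
  sets <- lapply(cover$coalitions, `[[`, "members")
  tibble::tibble(
    node = c(unlist(sets, use.names = FALSE), cover$residual),
    cluster = c(
      rep(sprintf("C%d", seq_along(sets)), lengths(sets)),
      if (length(cover$residual)) paste0("s_", cover$residual) else character()
    )
  )
}

#' Predicted complexes of a cover
#'
#' Extracts the coalition member sets as a `complex_set` for the
#' contingency-based metrics. Residual singletons are not counted as
#' predicted complexes unless `include_singletons` is set.
#'
#' @param cover A `pdc_cover`.
#' @param include_singletons Append each residual vertex as a singleton
#'   predicted complex?
#' @return A `complex_set`.
#' @export
cover_complexes <- function(cover, include_singletons = FALSE) {
  if (!inherits(cover, "pdc_cover")) {
    rlang::abort("`cover` must be a pdc_cover.")
  }
  sets <- lapply(cover$coalitions, `[[`, "members")
  if (include_singletons) {
    sets <- c(sets, as.list(cover$residual))
  }
  complex_set(sets, name = "predicted")
}

#' Normalized mutual information between two partitions
#'
#' Entropy-based similarity between two partitions of the same node set:
#' twice the mutual information of the class labels divided by the sum of
#' the two class entropies. Ranges from 0 (independent) to 1 (identical
#' partitions). When both partitions consist of a single class the measure
#' is 0/0 and is defined as 1 (the partitions are identical).
#'
#' @param a,b Partitions of the same universe: two-column data frames
#'   (node, class), lists of disjoint member sets, or `pdc_cover` objects
#'   (whose residual vertices enter as singleton classes).
#' @return A number in `[0, 1]`.
#' @examples
#' truth <- data.frame(node = letters[1:4], module = c("x", "x", "y", "y"))
#' nmi(truth, truth)
#' @export
nmi <- function(a, b) {
  ma <- as_membership(a, "a")
  mb <- as_membership(b, "b")
  if (length(ma) != length(mb) ||
      !setequal(names(ma), names(mb))) {
    rlang::abort("`a` and `b` must partition the same set of nodes.")
  }
  mb <- mb[names(ma)]
  n <- length(ma)
  tab <- table(ma, mb)
  ni <- rowSums(tab)
  nj <- colSums(tab)
  ha <- -sum((ni / n) * log(ni / n))
  hb <- -sum((nj / n) * log(nj / n))
  if (ha + hb == 0) {
    return(1)
  }
  nz <- tab > 0
  mi <- sum((tab[nz] / n) * log(tab[nz] * n / (ni[row(tab)[nz]] * nj[col(tab)[nz]])))
  2 * mi / (ha + hb)
}

#' Contingency table between predicted and reference complexes
#'
#' Builds the overlap-count table underlying the sensitivity / positive
#' predictive value metrics: entry `(j, i)` is the number of proteins shared
#' by reference complex `j` and predicted complex `i`.
#'
#' @param pred,ref Complex sets: `complex_set` objects, lists of member
#'   sets, or a `pdc_cover` for `pred`.
#' @return A `pdc_contingency` list with `t` (matrix, rows = reference),
#'   `ref_sizes` (reference complex sizes `N_j`) and `col_sums`
#'   (`T_.i`, column marginals).
#' @export
contingency <- function(pred, ref) {
  p <- as_complex_list(pred, "pred")
  r <- as_complex_list(ref, "ref")
  tab <- matrix(0L, nrow = length(r), ncol = length(p))
  for (j in seq_along(r)) {
    for (i in seq_along(p)) {
      tab[j, i] <- length(intersect(r[[j]], p[[i]]))
    }
  }
  structure(
    list(t = tab, ref_sizes = lengths(r), col_sums = colSums(tab)),
    class = "pdc_contingency"
  )
}

#' Jaccard matching score between predicted and reference complexes
#'
#' For every predicted complex the best Jaccard overlap with any reference
#' complex is found, and vice versa; `S` and `T` are the two directional
#' averages and the matching score `D = sqrt(S * T)` is their geometric
#' mean.
#'
#' @inheritParams contingency
#' @return A one-row tibble with columns `D`, `S`, `T`.
#' @examples
#' matching_score(list(c("a", "b", "c")), list(c("b", "c", "d")))
#' @export
matching_score <- function(pred, ref) {
  p <- as_complex_list(pred, "pred")
  r <- as_complex_list(ref, "ref")
  o <- matrix(0, nrow = length(r), ncol = length(p))
  for (j in seq_along(r)) {
    for (i in seq_along(p)) {
      inter <- length(intersect(r[[j]], p[[i]]))
      o[j, i] <- inter / (length(r[[j]]) + length(p[[i]]) - inter)
    }
  }
  S <- mean(apply(o, 2, max))
  T_ <- mean(apply(o, 1, max))
  tibble::tibble(D = sqrt(S * T_), S = S, T = T_)
}

#' Complex-wise sensitivity, positive predictive value and accuracy
#'
#' On the prediction-reference contingency table: the general sensitivity is
#' the reference-size-weighted mean of the per-reference best recovery,
#' `Sn = sum_j max_i t_ji / sum_j N_j`; the general positive predictive
#' value is the column-marginal-weighted mean of the per-prediction best
#' purity, `PPV = sum_i max_j t_ji / sum_i T_.i` (columns with `T_.i = 0`
#' contribute to neither sum); and the geometric accuracy is
#' `Acc = sqrt(Sn * PPV)`.
#'
#' @param x A `pdc_contingency` from [contingency()], or a predicted complex
#'   set (in which case `ref` must be supplied and the table is built first).
#' @param ref Reference complexes, when `x` is not already a table.
#' @return A one-row tibble with columns `Sn`, `PPV`, `Acc`.
#' @examples
#' sn_ppv_acc(contingency(list(c("a", "b")), list(c("a", "b"))))
#' @export
sn_ppv_acc <- function(x, ref = NULL) {
  tab <- if (inherits(x, "pdc_contingency")) x else contingency(x, ref)
  t_ <- tab$t
  if (all(t_ == 0)) {
    rlang::abort("All overlaps are zero: PPV is undefined.")
  }
  sn <- sum(apply(t_, 1, max)) / sum(tab$ref_sizes)
  keep <- tab$col_sums > 0
  ppv <- sum(apply(t_[, keep, drop = FALSE], 2, max)) / sum(tab$col_sums[keep])
  tibble::tibble(Sn = sn, PPV = ppv, Acc = sqrt(sn * ppv))
}

#' Connectivity density of a module
#'
#' The sum of within-module degrees of the module's members divided by the
#' total number of edges in the network. A module equal to the whole graph
#' scores 2 (handshake lemma); a module with no internal edges scores 0.
#'
#' @param graph A PPI network with at least one edge.
#' @param module Character vector of member identifiers.
#' @return A non-negative number.
#' @export
connectivity_density <- function(graph, module) {
  g <- as_ppi_network(graph)
  if (igraph::ecount(g) == 0) {
    rlang::abort("The graph has no edges: connectivity density is undefined.")
  }
  module <- unique(as.character(module))
  missing <- setdiff(module, igraph::V(g)$name)
  if (length(missing) > 0) {
    rlang::abort(sprintf("Not in graph: %s", paste(missing, collapse = ", ")))
  }
  sub <- igraph::induced_subgraph(g, module)
  sum(igraph::degree(sub)) / igraph::ecount(g)
}

#' Randomly shift a module
#'
#' Replaces a fraction of a module's members with vertices from outside the
#' module: `ceiling(fraction * |module|)` members are removed uniformly at
#' random and the same number of outside vertices — each adjacent to at
#' least one remaining member — are added uniformly at random. The module
#' size is preserved. For a genuinely dense module a small shift is expected
#' to decrease the connectivity density.
#'
#' @param graph A PPI network.
#' @param module Character vector of member identifiers.
#' @param fraction Fraction of members to replace, in `(0, 1)`.
#' @param seed Optional integer seed.
#' @return A radix-sorted character vector: the shifted module.
#' @export
shift_module <- function(graph, module, fraction, seed = NULL) {
  g <- as_ppi_network(graph)
  module <- unique(as.character(module))
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    rlang::abort("`fraction` must be strictly between 0 and 1.")
  }
  missing <- setdiff(module, igraph::V(g)$name)
  if (length(missing) > 0) {
    rlang::abort(sprintf("Not in graph: %s", paste(missing, collapse = ", ")))
  }
  r <- ceiling(fraction * length(module))
  draw <- function() {
    removed <- module[sample.int(length(module), r)]
    kept <- setdiff(module, removed)
    nbrs <- if (length(kept) > 0) {
      unique(unlist(lapply(
        igraph::adjacent_vertices(g, kept), function(vs) vs$name
      )))
    } else {
      character()
    }
    eligible <- setdiff(nbrs, module)
    if (length(eligible) < r) {
      rlang::abort(sprintf(
        "Not enough eligible replacement vertices: need %d, found %d.",
        r, length(eligible)
      ))
    }
    added <- eligible[sample.int(length(eligible), r)]
    sort(c(kept, added), method = "radix")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Evaluate predicted complexes against a reference set
#'
#' One-stop structural evaluation: Jaccard matching score with its
#' components, complex-wise sensitivity, positive predictive value and
#' accuracy, and (when a graph is supplied) the mean connectivity density of
#' the predicted complexes.
#'
#' @param pred Predicted complexes (`pdc_cover`, `complex_set`, or list).
#' @param ref Reference complexes.
#' @param graph Optional PPI network for connectivity density.
#' @return A one-row tibble with columns `n_pred`, `n_ref`, `D`, `S`, `T`,
#'   `Sn`, `PPV`, `Acc` and, when `graph` is given,
#'   `mean_connectivity_density`.
#' @export
evaluate_complexes <- function(pred, ref, graph = NULL) {
  p <- as_complex_list(pred, "pred")
  r <- as_complex_list(ref, "ref")
  ms <- matching_score(p, r)
  sp <- sn_ppv_acc(contingency(p, r))
  out <- dplyr::bind_cols(
    tibble::tibble(n_pred = length(p), n_ref = length(r)),
    ms, sp
  )
  if (!is.null(graph)) {
    g <- as_ppi_network(graph)
    out$mean_connectivity_density <-
      mean(vapply(p, function(s) connectivity_density(g, s), numeric(1)))
  }
  out
}
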