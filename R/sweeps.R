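# Derive a stream of reproducible sub-seeds from one master seed, keeping
# everything inside the 32-bit integer range.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Detect complexes in an edge-list file and write them out
#'
#' Reads a network, plays the coalition game, optionally writes the detected
#' complexes to a membership file, and logs node/edge counts, parameters,
#' coalition count, residual size and wall time.
#'
#' @param input Path to an edge-list file, or a PPI network object.
#' @param output Optional output path for [write_cover_set()].
#' @param config A [pdc_config()].
#' @param dialect Edge-list dialect, `"tsv"` or `"sif"`.
#' @param include_singletons Write residual vertices as singleton lines?
#' @param quiet Suppress log messages?
#' @return The `pdc_cover`, invisibly when `output` is written.
#' @export
run_detect <- function(input, output = NULL, config = pdc_config(),
                       dialect = "tsv", include_singletons = FALSE,
                       quiet = FALSE) {
  g <- if (is.character(input)) read_edge_list(input, dialect) else as_ppi_network(input)
  say <- function(...) if (!quiet) rlang::inform(sprintf(...))
  say("Network: %d nodes, %d edges.", igraph::vcount(g), igraph::ecount(g))
  say("Parameters: lambda = %g, gamma = %g, p = %d, min_size = %d.",
      config$lambda, config$gamma, config$p, config$min_size)
  if (igraph::ecount(g) == 0) {
    rlang::warn("The network has no edges; every node will be residual.")
  }
  t0 <- proc.time()[["elapsed"]]
  cover <- nash_pdc(g, config)
  say("Detected %d coalition(s); %d residual node(s); %.2f s elapsed.",
      length(cover$coalitions), length(cover$residual),
      proc.time()[["elapsed"]] - t0)
  if (!is.null(output)) {
    write_cover_set(cover, output, include_singletons = include_singletons)
    say("Wrote '%s'.", output)
    return(invisible(cover))
  }
  cover
}

new_sweep <- function(df, var) {
  structure(df, class = c("pdc_sweep", class(df)), sweep_var = var)
}

#' Mixing-parameter sweep on Girvan-Newman benchmarks
#'
#' For each value of the mixing parameter `mu`, generates `instances`
#' planted-partition networks with distinct derived seeds, detects
#' complexes, and scores each run by [nmi()] between the planted partition
#' and the detected partition (residual vertices as singleton classes).
#'
#' @param mu_grid Mixing-parameter grid, values in `[0, 1]`.
#' @param instances Networks per grid point.
#' @param config A [pdc_config()].
#' @param seed Master seed; per-instance seeds are derived from it.
#' @inheritParams generate_gn
#' @return A tibble (class `pdc_sweep`) with columns `mu`, `mean_nmi`,
#'   `sd_nmi`, `mean_coalitions`, `n_instances`.
#' @export
run_gn_sweep <- function(mu_grid = seq(0.1, 0.7, by = 0.1), instances = 100,
                         config = pdc_config(), n_nodes = 128, n_modules = 4,
                         module_size = 32, avg_degree = 16, seed = 1) {
  stopifnot(length(mu_grid) > 0, all(mu_grid >= 0 & mu_grid <= 1), instances >= 1)
  seeds <- matrix(derive_seeds(seed, length(mu_grid) * instances),
                  nrow = instances)
  rows <- purrr::imap(mu_grid, function(mu, j) {
    scores <- vapply(seq_len(instances), function(i) {
      net <- generate_gn(mu, n_nodes, n_modules, module_size, avg_degree,
                         seed = seeds[i, j])
      cover <- nash_pdc(net$graph, config)
      c(nmi(net$truth, cover_partition(cover)), length(cover$coalitions))
    }, numeric(2))
    tibble::tibble(
      mu = mu,
      mean_nmi = mean(scores[1, ]),
      sd_nmi = stats::sd(scores[1, ]),
      mean_coalitions = mean(scores[2, ]),
      n_instances = instances
    )
  })
  new_sweep(dplyr::bind_rows(rows), "mu")
}

#' Rewiring-probability sweep on perturbed benchmarks
#'
#' Generates Girvan-Newman base networks at low mixing, perturbs each by
#' [rewire_edges()] at every rewiring probability in `rho_grid`, detects
#' complexes on the perturbed network, and scores against the original
#' planted partition.
#'
#' @param rho_grid Rewiring-probability grid, values in `[0, 1]`.
#' @param mu Mixing parameter of the base networks.
#' @param instances Base networks per grid point.
#' @inheritParams run_gn_sweep
#' @return A tibble (class `pdc_sweep`) with columns `rho`, `mean_nmi`,
#'   `sd_nmi`, `mean_coalitions`, `n_instances`.
#' @export
run_rewire_sweep <- function(rho_grid = c(0, 0.05, 0.1, 0.25, 0.4), mu = 0.1,
                             instances = 100, config = pdc_config(),
                             n_nodes = 128, n_modules = 4, module_size = 32,
                             avg_degree = 16, seed = 1) {
  stopifnot(length(rho_grid) > 0, all(rho_grid >= 0 & rho_grid <= 1), instances >= 1)
  seeds <- derive_seeds(seed, instances * (1 + length(rho_grid)))
  base_seeds <- seeds[seq_len(instances)]
  rew_seeds <- matrix(seeds[-seq_len(instances)], nrow = instances)
  nets <- lapply(base_seeds, function(s) {
    generate_gn(mu, n_nodes, n_modules, module_size, avg_degree, seed = s)
  })
  rows <- purrr::imap(rho_grid, function(rho, j) {
    scores <- vapply(seq_len(instances), function(i) {
      pg <- rewire_edges(nets[[i]]$graph, rho, seed = rew_seeds[i, j])
      cover <- nash_pdc(pg, config)
      c(nmi(nets[[i]]$truth, cover_partition(cover)), length(cover$coalitions))
    }, numeric(2))
    tibble::tibble(
      rho = rho,
      mean_nmi = mean(scores[1, ]),
      sd_nmi = stats::sd(scores[1, ]),
      mean_coalitions = mean(scores[2, ]),
      n_instances = instances
    )
  })
  new_sweep(dplyr::bind_rows(rows), "rho")
}

#' Null-model experiment on Erdos-Renyi graphs
#'
#' Runs the coalition game on random G(n, p) graphs matched in size and
#' density to the planted benchmarks and reports what, if anything, was
#' detected in each instance.
#'
#' @param instances Number of random graphs.
#' @param n_nodes Vertices per graph.
#' @param edge_prob Edge probability (default matches a 128-node graph of
#'   expected degree 16).
#' @param config A [pdc_config()].
#' @param seed Master seed.
#' @return A tibble with columns `instance`, `seed`, `n_coalitions`,
#'   `largest_coalition`, `n_residual`.
#' @export
run_er_null <- function(instances = 20, n_nodes = 128, edge_prob = 16 / 127,
                        config = pdc_config(), seed = 1) {
  seeds <- derive_seeds(seed, instances)
  rows <- purrr::map(seq_len(instances), function(i) {
    g <- generate_er(n_nodes, edge_prob, seed = seeds[i])
    cover <- nash_pdc(g, config)
    sizes <- vapply(cover$coalitions, function(co) length(co$members), integer(1))
    tibble::tibble(
      instance = i,
      seed = seeds[i],
      n_coalitions = length(cover$coalitions),
      largest_coalition = if (length(sizes)) max(sizes) else 0L,
      n_residual = length(cover$residual)
    )
  })
  dplyr::bind_rows(rows)
}

#' Module-shift experiment: does shifting decrease connectivity density?
#'
#' For each module, repeatedly replaces a fraction of its members with
#' adjacent outside vertices ([shift_module()]) and compares the mean
#' connectivity density of the shifted modules with the original. For a
#' genuinely dense module the shift is expected to decrease the density.
#'
#' @param graph A PPI network, or `NULL` to generate a Girvan-Newman
#'   benchmark at mixing `mu` and use its planted modules.
#' @param modules A list of member-identifier vectors; defaults to the
#'   planted modules when `graph` is `NULL`.
#' @param fraction Fraction of members replaced per shift.
#' @param replicates Randomisation replicates per module.
#' @param mu Mixing parameter of the generated benchmark (when `graph` is
#'   `NULL`).
#' @param seed Master seed.
#' @return A tibble with columns `module`, `size`, `density`,
#'   `mean_shifted_density`, `sd_shifted_density`, `replicates`.
#' @export
run_shift_test <- function(graph = NULL, modules = NULL, fraction = 0.2,
                           replicates = 300, mu = 0.2, seed = 1) {
  if (is.null(graph)) {
    net <- generate_gn(mu, seed = derive_seeds(seed, 1))
    graph <- net$graph
    if (is.null(modules)) {
      modules <- split(net$truth$node, net$truth$module)
    }
  }
  if (is.null(modules)) {
    rlang::abort("Supply `modules` when `graph` is given.")
  }
  g <- as_ppi_network(graph)
  seeds <- matrix(derive_seeds(seed + 1, length(modules) * replicates),
                  nrow = replicates)
  rows <- purrr::imap(modules, function(mod, k) {
    j <- if (is.character(k)) match(k, names(modules)) else k
    shifted <- vapply(seq_len(replicates), function(i) {
      connectivity_density(g, shift_module(g, mod, fraction, seed = seeds[i, j]))
    }, numeric(1))
    tibble::tibble(
      module = if (is.character(k)) k else sprintf("module%d", k),
      size = length(mod),
      density = connectivity_density(g, mod),
      mean_shifted_density = mean(shifted),
      sd_shifted_density = stats::sd(shifted),
      replicates = replicates
    )
  })
  dplyr::bind_rows(rows)
}
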