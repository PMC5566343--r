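#' Tidy a detected cover into a per-coalition table
#'
#' @param x A `pdc_cover` from [nash_pdc()].
#' @param ... Unused.
#' @return A tibble with one row per coalition: `coalition`, `size`,
#'   `proposer`, `min_within_degree`, `degree_density`, `edge_density`,
#'   `diameter`.
#' @export
tidy.pdc_cover <- function(x, ...) {
  if (length(x$coalitions) == 0) {
    return(tibble::tibble(
      coalition = character(), size = integer(), proposer = character(),
      min_within_degree = integer(), degree_density = double(),
      edge_density = double(), diameter = double()
    ))
  }
  dplyr::bind_rows(purrr::imap(x$coalitions, function(co, i) {
    tibble::tibble(
      coalition = sprintf("C%d", i),
      size = co$stats$size,
      proposer = co$proposer,
      min_within_degree = co$stats$min_within_degree,
      degree_density = co$stats$degree_density,
      edge_density = co$stats$edge_density,
      diameter = co$stats$diameter
    )
  }))
}

#' One-row summary of a detected cover
#'
#' @param x A `pdc_cover`.
#' @param ... Unused.
#' @return A one-row tibble: `n_nodes`, `n_coalitions`, `n_assigned`,
#'   `n_residual`, `coverage`, `lambda`, `gamma`, `p`, `min_size`.
#' @export
glance.pdc_cover <- function(x, ...) {
  assigned <- sum(vapply(x$coalitions, function(co) length(co$members), integer(1)))
  tibble::tibble(
    n_nodes = x$n_nodes,
    n_coalitions = length(x$coalitions),
    n_assigned = assigned,
    n_residual = length(x$residual),
    coverage = assigned / x$n_nodes,
    lambda = x$config$lambda,
    gamma = x$config$gamma,
    p = x$config$p,
    min_size = x$config$min_size
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the coalitions of a detected cover
#'
#' Scatter of each coalition's degree density against its edge density,
#' point size proportional to coalition size, with the configured floors
#' drawn as dashed lines.
#'
#' @param object A `pdc_cover`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pdc_cover <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$edge_density,
                                   y = .data$degree_density,
                                   size = .data$size)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = object$config$gamma, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$config$lambda, linetype = "dashed") +
    ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::labs(
      x = "edge density (delta)", y = "degree density (alpha)",
      size = "members",
      title = sprintf("%d coalition(s), %d residual node(s)",
                      length(object$coalitions), length(object$residual))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a benchmark sweep
#'
#' Mean NMI (with a one-standard-deviation ribbon) against the swept
#' parameter (mixing `mu` or rewiring probability `rho`).
#'
#' @param object A `pdc_sweep` tibble from [run_gn_sweep()] or
#'   [run_rewire_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pdc_sweep <- function(object, ...) {
  var <- attr(object, "sweep_var")
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[var]], y = .data$mean_nmi)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(0, .data$mean_nmi - .data$sd_nmi),
                   ymax = pmin(1, .data$mean_nmi + .data$sd_nmi)),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::lims(y = c(0, 1)) +
    ggplot2::labs(x = var, y = "mean NMI") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
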