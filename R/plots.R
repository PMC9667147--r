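#' Plot a daily network state series
#'
#' Three stacked panels: discharge, persistency threshold and relative
#' active length (with the largest connected patch overlaid).
#'
#' @param object A `network_state_series`.
#' @param days Optional day range to display, e.g. `1:365`.
#' @param ... Unused.
#' @return A ggplot object (facetted).
#' @method autoplot network_state_series
#' @export
autoplot.network_state_series <- function(object, days = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(days)) df <- dplyr::filter(df, .data$day %in% days)
  lg <- geomorphic_length(attr(object, "network"))
  long <- dplyr::bind_rows(
    tibble::tibble(day = df$day, value = df$q,
                   panel = "discharge Q (mm/d)", series = "Q"),
    tibble::tibble(day = df$day, value = df$p_star,
                   panel = "persistency threshold P*", series = "P*"),
    tibble::tibble(day = df$day, value = df$relative_length,
                   panel = "relative length", series = "L / Lg"),
    tibble::tibble(day = df$day, value = df$lcp_length / lg,
                   panel = "relative length", series = "LCP / Lg")
  )
  long$panel <- factor(long$panel, levels = unique(long$panel))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "day", y = NULL, colour = NULL)
}

#' Plot flow or stream-length duration curves
#'
#' Duration on the x axis, the ranked quantity on the y axis. For a
#' `streamdyn_run` the empirical stream length duration curve is drawn
#' together with its analytic counterpart `(1 - D)^beta`.
#'
#' @param run A `streamdyn_run`.
#' @return A ggplot object.
#' @export
plot_sldc <- function(run) {
  beta <- run$climate$beta
  grid <- tibble::tibble(duration = seq(0, 1, by = 0.005))
  grid$relative_length <- sldc_analytic(grid$duration, beta = beta)
  ggplot2::ggplot(run$sldc,
                  ggplot2::aes(x = .data$duration, y = .data$relative_length)) +
    ggplot2::geom_step(ggplot2::aes(colour = "empirical")) +
    ggplot2::geom_line(data = grid, ggplot2::aes(colour = "analytic"),
                       linetype = 2) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "duration D", y = "relative length L / Lg",
                  colour = NULL)
}

#' @rdname plot_sldc
#' @export
plot_fdc <- function(run) {
  cl <- run$climate
  grid <- analytic_fdc(cl$alpha, cl$lambda_eff, cl$k)
  ggplot2::ggplot(run$fdc, ggplot2::aes(x = .data$duration, y = .data$q)) +
    ggplot2::geom_step(ggplot2::aes(colour = "empirical")) +
    ggplot2::geom_line(data = grid, ggplot2::aes(colour = "analytic"),
                       linetype = 2) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "duration D", y = "discharge Q (mm/d)", colour = NULL)
}

#' Plot the largest-connected-patch curve of a run
#'
#' Relative LCP length (and total active length) against the persistency
#' threshold, read right to left as the network expands from fully dry
#' (`P* = 1`) to fully wet (`P* -> 0`).
#'
#' @param run A `streamdyn_run`.
#' @return A ggplot object.
#' @export
plot_lcp <- function(run) {
  long <- tidyr::pivot_longer(run$lcp,
                              c("relative_length", "relative_lcp_length"),
                              names_to = "series", values_to = "value")
  long$series <- ifelse(long$series == "relative_length", "L / Lg", "LCP / Lg")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$p_star, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "persistency threshold P*", y = "relative length",
                  colour = NULL)
}

#' @method autoplot streamdyn_run
#' @export
autoplot.streamdyn_run <- function(object, days = NULL, ...) {
  autoplot(object$state, days = days, ...)
}
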