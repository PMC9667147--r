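#' Stochastic streamflow simulation
#'
#' Generates a daily discharge series from the jump--decay process
#' `dQ/dt = -k Q + xi(t)`: effective rainfall arrives as a marked Poisson
#' process of frequency `lambda` whose events add exponentially distributed
#' streamflow jumps (mean `alpha * k` in discharge units, so that the
#' long-run water balance gives `mean(Q) = alpha * lambda`), and discharge
#' recedes exponentially at rate `k` in between. The continuous-time process
#' is simulated exactly — events are placed uniformly within each day and
#' decayed by their remaining fraction of the day — and sampled at the end
#' of each day, so the sampled marginal follows the stationary gamma law
#' with shape `lambda/k` and scale `alpha*k` without discretisation bias.
#'
#' @param alpha Mean effective rainfall depth (mm/d), > 0.
#' @param lambda Effective rainfall frequency (1/d), >= 0 (`lambda = 0`
#'   yields a pure recession, useful for checks).
#' @param k Recession rate (1/d), > 0.
#' @param n_days Number of simulated days (>= 1). A 100-year run is
#'   `36500` days (no leap days; time is a day index, not a calendar).
#' @param seed Integer seed; the realisation is deterministic given the seed.
#' @param q0 Initial condition: `"stationary"` (default) draws `Q(0)` from
#'   the stationary gamma so no burn-in is needed; `"zero"` starts dry; a
#'   number fixes `Q(0)` exactly.
#' @param keep_events If `TRUE`, attach the event log (day, within-day time,
#'   jump size) as attribute `events`.
#' @return A tibble with columns `day` (1-based integer) and `q` (mm/d),
#'   of class `streamflow_series`, with the generating parameters stored in
#'   attribute `params`.
#' @examples
#' q <- simulate_streamflow(15, 0.0972, 0.35, n_days = 365, seed = 1)
#' mean(q$q)
#' @export
simulate_streamflow <- function(alpha, lambda, k, n_days, seed = NULL,
                                q0 = "stationary", keep_events = FALSE) {
  if (alpha <= 0 || lambda < 0 || k <= 0) {
    rlang::abort("require alpha > 0, lambda >= 0, k > 0",
                 class = "streamdyn_argument_error")
  }
  if (!is.numeric(n_days) || length(n_days) != 1 || n_days < 1 ||
      n_days != round(n_days)) {
    rlang::abort("n_days must be a positive integer",
                 class = "streamdyn_argument_error")
  }
  n_days <- as.integer(n_days)
  if (!is.null(seed)) set.seed(seed)
  q_init <- if (identical(q0, "stationary")) {
    if (lambda <= 0) {
      rlang::abort("stationary initial condition requires lambda > 0",
                   class = "streamdyn_argument_error")
    }
    stats::rgamma(1, shape = lambda / k, scale = alpha * k)
  } else if (identical(q0, "zero")) {
    0
  } else if (is.numeric(q0) && length(q0) == 1 && q0 >= 0) {
    q0
  } else {
    rlang::abort("q0 must be \"stationary\", \"zero\" or a non-negative number",
                 class = "streamdyn_argument_error")
  }
  n_events <- stats::rpois(n_days, lambda)
  m <- sum(n_events)
  day_of <- rep.int(seq_len(n_days), n_events)
  u <- stats::runif(m)                       # event time within its day
  jump <- stats::rexp(m, rate = 1 / (alpha * k))
  # contribution of each event to its day-end discharge
  increments <- jump * exp(-k * (1 - u))
  daily_input <- numeric(n_days)
  if (m > 0) {
    agg <- rowsum(increments, day_of)
    daily_input[as.integer(rownames(agg))] <- agg[, 1]
  }
  decay <- exp(-k)
  q <- as.numeric(stats::filter(daily_input, decay, method = "recursive"))
  q <- q + q_init * decay^seq_len(n_days)
  out <- tibble::tibble(day = seq_len(n_days), q = q)
  class(out) <- c("streamflow_series", class(out))
  attr(out, "params") <- list(alpha = alpha, lambda = lambda, k = k,
                              q0 = q0, seed = seed)
  if (keep_events) {
    attr(out, "events") <- tibble::tibble(day = day_of, time = u, jump = jump)
  }
  out
}

flow_params <- function(series) {
  p <- attr(series, "params")
  if (is.null(p)) {
    rlang::abort("series carries no flow-model parameters",
                 class = "streamdyn_argument_error")
  }
  p
}

#' Stationary distribution of daily streamflow
#'
#' The marginal law of the jump--decay streamflow process is a gamma
#' distribution with shape `lambda/k` and scale `alpha*k`; its CDF links
#' every discharge to its non-exceedance probability and hence (via
#' `D = 1 - CDF`) to the flow duration curve.
#'
#' @param q Discharge (mm/d), >= 0. Vectorised.
#' @param p Probability in \[0, 1\]. Vectorised.
#' @param alpha Mean effective rainfall depth (mm/d).
#' @param lambda Effective rainfall frequency (1/d), > 0.
#' @param k Recession rate (1/d).
#' @return `flow_cdf()` returns non-exceedance probabilities;
#'   `flow_quantile()` its inverse.
#' @examples
#' flow_cdf(3.5, alpha = 10, lambda = 0.35, k = 0.35)  # 1 - exp(-1)
#' @export
flow_cdf <- function(q, alpha, lambda, k) {
  if (any(q < 0)) {
    rlang::abort("q must be >= 0", class = "streamdyn_argument_error")
  }
  if (alpha <= 0 || lambda <= 0 || k <= 0) {
    rlang::abort("require alpha > 0, lambda > 0, k > 0",
                 class = "streamdyn_argument_error")
  }
  stats::pgamma(q, shape = lambda / k, scale = alpha * k)
}

#' @rdname flow_cdf
#' @export
flow_quantile <- function(p, alpha, lambda, k) {
  check_unit_interval(p, "p")
  stats::qgamma(p, shape = lambda / k, scale = alpha * k)
}

#' Empirical flow duration curve
#'
#' Ranks the daily discharges in descending order and assigns the j-th
#' largest value the Weibull exceedance duration `j/(n+1)`; tied values
#' share the largest (most conservative) duration among their ranks.
#'
#' @param series A `streamflow_series`, or a numeric vector of discharges.
#' @return A tibble of class `flow_duration_curve` with columns `q`
#'   (descending) and `duration` in (0, 1), carrying the sample size as
#'   attribute `n`.
#' @examples
#' empirical_fdc(c(3, 1, 2))
#' @export
empirical_fdc <- function(series) {
  q <- if (is.data.frame(series)) series$q else as.numeric(series)
  if (length(q) < 1) {
    rlang::abort("empty discharge series", class = "streamdyn_argument_error")
  }
  n <- length(q)
  out <- tibble::tibble(q = sort(q, decreasing = TRUE)) |>
    dplyr::mutate(position = dplyr::row_number()) |>
    dplyr::group_by(.data$q) |>
    dplyr::mutate(duration = max(.data$position) / (n + 1)) |>
    dplyr::ungroup() |>
    dplyr::select("q", "duration")
  class(out) <- c("flow_duration_curve", class(out))
  attr(out, "n") <- n
  attr(out, "params") <- attr(series, "params")
  out
}

#' Query a flow duration curve
#'
#' Exceedance duration of an arbitrary discharge against an empirical FDC,
#' using step (exceedance-count) interpolation: `D(q)` is the number of
#' sample values `>= q` over `n + 1`, clamped to
#' `[1/(n+1), n/(n+1)]` so durations stay strictly inside (0, 1).
#'
#' @param fdc A `flow_duration_curve` from [empirical_fdc()].
#' @param q Discharge value(s) to query.
#' @return Duration(s) in (0, 1).
#' @export
fdc_duration <- function(fdc, q) {
  n <- attr(fdc, "n")
  asc <- rev(fdc$q)  # ascending
  n_ge <- n - findInterval(q, asc, left.open = TRUE)
  pmin(pmax(n_ge, 1L), n) / (n + 1)
}

#' Analytic flow duration curve as a tibble
#'
#' Evaluates `D(Q) = 1 - CDF(Q)` of the stationary gamma law on a grid of
#' discharges, for plotting and export alongside empirical curves.
#'
#' @inheritParams flow_cdf
#' @param q_max Upper end of the discharge grid; defaults to the 0.999
#'   quantile.
#' @param n_grid Number of grid points.
#' @return A tibble with columns `q` and `duration`.
#' @export
analytic_fdc <- function(alpha, lambda, k, q_max = NULL, n_grid = 512) {
  if (is.null(q_max)) q_max <- flow_quantile(0.999, alpha, lambda, k)
  q <- seq(0, q_max, length.out = n_grid)
  tibble::tibble(q = q, duration = 1 - flow_cdf(q, alpha, lambda, k))
}
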