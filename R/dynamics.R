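#' Persistency threshold series from streamflow
#'
#' Transforms a discharge series into the daily persistency threshold
#' `P*(t) = D(Q(t)) = 1 - CDF_Q(Q(t))`: high flows map to low thresholds
#' (expanded network), low flows to high thresholds (contracted network).
#' In `"empirical"` mode (two-pass, the default) each day receives the
#' Weibull exceedance position of its own discharge within the simulated
#' series, `rank/(n+1)`; in `"analytic"` mode the stationary gamma CDF is
#' evaluated, which requires the generating parameters.
#'
#' @param series A `streamflow_series` (or tibble with columns `day`, `q`).
#' @param fdc_mode `"empirical"` or `"analytic"`.
#' @param alpha,lambda,k Flow-model parameters for analytic mode; taken
#'   from the series attributes when omitted.
#' @return A tibble with columns `day`, `q` and `p_star`.
#' @export
persistency_threshold <- function(series, fdc_mode = c("empirical", "analytic"),
                                  alpha = NULL, lambda = NULL, k = NULL) {
  fdc_mode <- match.arg(fdc_mode)
  df <- tibble::as_tibble(series)
  q <- df$q
  n <- length(q)
  if (n < 1) {
    rlang::abort("empty discharge series", class = "streamdyn_argument_error")
  }
  if (fdc_mode == "empirical") {
    # Weibull exceedance position; ties share the largest duration
    n_ge <- n - rank(q, ties.method = "min") + 1L
    p_star <- pmin(pmax(n_ge, 1L), n) / (n + 1)
  } else {
    p <- attr(series, "params")
    alpha <- alpha %||% p$alpha
    lambda <- lambda %||% p$lambda
    k <- k %||% p$k
    p_star <- 1 - flow_cdf(q, alpha, lambda, k)
  }
  tibble::tibble(day = df$day %||% seq_len(n), q = q, p_star = p_star)
}

#' Node states at a given persistency threshold
#'
#' Under hierarchical structuring a node is active exactly when its local
#' persistency reaches the threshold: `X_i = 1` iff `P_i >= p_star`
#' (inclusive).
#'
#' @param network A `stream_network` with a `persistency` column, or a
#'   numeric vector of persistencies.
#' @param p_star A single threshold in (0, 1\].
#' @return An integer 0/1 vector, one element per node.
#' @export
node_status <- function(network, p_star) {
  p <- if (is.data.frame(network)) network$persistency else network
  if (is.null(p)) {
    rlang::abort("network carries no persistency field",
                 class = "streamdyn_argument_error")
  }
  if (length(p_star) != 1 || p_star <= 0 || p_star > 1) {
    rlang::abort("p_star must be a single value in (0, 1]",
                 class = "streamdyn_argument_error")
  }
  as.integer(p >= p_star)
}

#' Active length of a network configuration
#'
#' Sum of the reach lengths of the active nodes,
#' `L = sum(reach_length * status)`; includes active reaches disconnected
#' from the outlet.
#'
#' @param status 0/1 vector, one element per node.
#' @param network The `stream_network` the status refers to.
#' @return Total active length (same units as `reach_length`).
#' @export
active_length <- function(status, network) {
  if (length(status) != nrow(network)) {
    rlang::abort("status length does not match the node count",
                 class = "streamdyn_argument_error")
  }
  sum(network$reach_length * status)
}

#' Analytic stream length duration curve
#'
#' Fraction of the geomorphic length active for at least a fraction `d` of
#' the time: `L/L_g = 1 - CDF_P(d) = (1 - d)^beta` on the temporary part,
#' plus the perennial atom if any. Strictly decreasing in `d`.
#' `sldc_inverse()` solves for the duration at which a given relative
#' length is sustained.
#'
#' @param d Duration(s) in \[0, 1\].
#' @param rel_length Relative length(s) in (0, 1\].
#' @inheritParams persistency_cdf
#' @return Relative lengths (for `sldc_analytic()`) or durations (for
#'   `sldc_inverse()`).
#' @examples
#' sldc_analytic(0.2, mean_persistency = 0.74)   # ~0.92 of the network
#' sldc_inverse(0.5, mean_persistency = 0.20)    # ~0.16
#' @export
sldc_analytic <- function(d, mean_persistency = NULL, beta = NULL,
                          perennial_fraction = 0) {
  check_unit_interval(d, "d")
  1 - persistency_cdf(d, mean_persistency = mean_persistency, beta = beta,
                      perennial_fraction = perennial_fraction)
}

#' @rdname sldc_analytic
#' @export
sldc_inverse <- function(rel_length, mean_persistency = NULL, beta = NULL) {
  beta <- resolve_beta(beta, mean_persistency)
  if (any(rel_length <= 0 | rel_length > 1)) {
    rlang::abort("rel_length must lie in (0, 1]",
                 class = "streamdyn_argument_error")
  }
  1 - rel_length^(1 / beta)
}

#' Empirical duration curve of a daily series
#'
#' Weibull plotting positions of any daily quantity (active length, LCP
#' length, discharge): the j-th largest value gets duration `j/(n+1)`,
#' ties sharing the largest position.
#'
#' @param values Numeric vector of daily values.
#' @return A tibble with columns `value` (descending) and `duration`.
#' @export
duration_curve <- function(values) {
  if (length(values) < 1) {
    rlang::abort("empty series", class = "streamdyn_argument_error")
  }
  n <- length(values)
  tibble::tibble(value = sort(values, decreasing = TRUE)) |>
    dplyr::mutate(position = dplyr::row_number()) |>
    dplyr::group_by(.data$value) |>
    dplyr::mutate(duration = max(.data$position) / (n + 1)) |>
    dplyr::ungroup() |>
    dplyr::select("value", "duration")
}

# Activation order: nodes sorted by decreasing persistency, ties by node_id.
activation_order <- function(network) {
  order(-network$persistency, network$node_id)
}

# Largest-connected-patch length for every nested configuration.
# Nodes activate in persistency order; connectivity is incremental
# (union-find with union by size and path halving), so lcp[k + 1] is the
# LCP length with the k most persistent nodes active.
lcp_by_count <- function(network) {
  n <- nrow(network)
  ord <- activation_order(network)
  ds <- match(network$downstream_id, network$node_id)
  # adjacency: downstream neighbour + upstream children
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(ds[i])) {
      adj[[i]] <- c(adj[[i]], ds[i])
      adj[[ds[i]]] <- c(adj[[ds[i]]], i)
    }
  }
  parent <- seq_len(n)
  find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  comp_len <- numeric(n)
  active <- rep(FALSE, n)
  lcp <- numeric(n + 1)
  cur_max <- 0
  for (step in seq_len(n)) {
    v <- ord[step]
    active[v] <- TRUE
    comp_len[v] <- network$reach_length[v]
    rv <- v
    for (w in adj[[v]]) {
      if (active[w]) {
        rw <- find(w)
        rv <- find(rv)
        if (rv != rw) {
          if (comp_len[rv] < comp_len[rw]) { tmp <- rv; rv <- rw; rw <- tmp }
          parent[rw] <- rv
          comp_len[rv] <- comp_len[rv] + comp_len[rw]
        }
      }
    }
    rv <- find(v)
    if (comp_len[rv] > cur_max) cur_max <- comp_len[rv]
    lcp[step + 1] <- cur_max
  }
  lcp
}

# Cumulative active length for every nested configuration (by activation
# count); cum_len[k + 1] is L with the k most persistent nodes active.
length_by_count <- function(network) {
  ord <- activation_order(network)
  c(0, cumsum(network$reach_length[ord]))
}

# Number of active nodes at each threshold (P_i >= p_star, inclusive).
active_count <- function(persistency, p_star) {
  sp <- sort(persistency)
  length(sp) - findInterval(p_star, sp, left.open = TRUE)
}

#' Largest-connected-patch curve
#'
#' For each persistency threshold in `p_star_grid`, activates the nodes
#' with `P_i >= p_star`, forms the subgraph induced by active nodes
#' (adjacency = network links between two active nodes, undirected), and
#' returns the summed reach length of the largest connected component,
#' together with the total active length. Under the contributing-area
#' allocation the active network is always a single patch, so
#' `lcp_length == active_length` everywhere.
#'
#' @param network A `stream_network` with a `persistency` column.
#' @param p_star_grid Thresholds in (0, 1\]; defaults to a uniform grid.
#' @return A tibble with columns `p_star`, `active_length`, `lcp_length`,
#'   `relative_length` and `relative_lcp_length`.
#' @export
lcp_curve <- function(network, p_star_grid = seq(0.005, 1, by = 0.005)) {
  if (!"persistency" %in% names(network)) {
    rlang::abort("network carries no persistency field",
                 class = "streamdyn_argument_error")
  }
  if (any(p_star_grid <= 0 | p_star_grid > 1)) {
    rlang::abort("p_star_grid values must lie in (0, 1]",
                 class = "streamdyn_argument_error")
  }
  lg <- geomorphic_length(network)
  lcp <- lcp_by_count(network)
  lens <- length_by_count(network)
  counts <- active_count(network$persistency, p_star_grid)
  tibble::tibble(
    p_star = p_star_grid,
    active_length = lens[counts + 1],
    lcp_length = lcp[counts + 1],
    relative_length = .data$active_length / lg,
    relative_lcp_length = .data$lcp_length / lg
  )
}

#' Simulate the daily dynamics of the active network
#'
#' The core driver: converts a discharge series into the daily persistency
#' threshold, switches node states under hierarchical structuring, and
#' tracks the active length and the largest-connected-patch length day by
#' day. Because configurations are nested (a threshold set), each day is
#' characterised by its active-node count; full binary status matrices are
#' reconstructable via [node_status()] and are not stored.
#'
#' @param network A `stream_network` with a `persistency` column
#'   (see [allocate_persistency()]).
#' @param series A `streamflow_series` (or a tibble with `day`, `q`
#'   columns, e.g. observed discharge read from file).
#' @inheritParams persistency_threshold
#' @return A tibble of class `network_state_series` with columns `day`, `q`,
#'   `p_star`, `n_active`, `active_length`, `relative_length`, `lcp_length`,
#'   the network stored in attribute `network`.
#' @export
simulate_network_dynamics <- function(network, series,
                                      fdc_mode = c("empirical", "analytic"),
                                      alpha = NULL, lambda = NULL, k = NULL) {
  fdc_mode <- match.arg(fdc_mode)
  if (!"persistency" %in% names(network)) {
    rlang::abort("network carries no persistency field",
                 class = "streamdyn_argument_error")
  }
  thr <- persistency_threshold(series, fdc_mode = fdc_mode,
                               alpha = alpha, lambda = lambda, k = k)
  lg <- geomorphic_length(network)
  lens <- length_by_count(network)
  lcp <- lcp_by_count(network)
  counts <- active_count(network$persistency, thr$p_star)
  out <- dplyr::mutate(thr,
                       n_active = counts,
                       active_length = lens[counts + 1],
                       relative_length = .data$active_length / lg,
                       lcp_length = lcp[counts + 1])
  class(out) <- c("network_state_series", class(out))
  attr(out, "network") <- network
  attr(out, "fdc_mode") <- fdc_mode
  out
}

#' Summary statistics of a network dynamics run
#'
#' One-row summary of a daily state series: mean and coefficient of
#' variation of the active length (population standard deviation), mean
#' relative length, and the most contracted / expanded configurations.
#'
#' @param state A `network_state_series` from [simulate_network_dynamics()].
#' @return A one-row tibble with columns `n_days`, `mean_length`, `cv_length`,
#'   `mean_relative_length`, `mean_lcp_length`, `min_length`, `max_length`.
#' @export
summarize_dynamics <- function(state) {
  l <- state$active_length
  n <- length(l)
  if (n < 2) {
    rlang::abort("need at least 2 days to summarise dynamics",
                 class = "streamdyn_argument_error")
  }
  m <- mean(l)
  if (m == 0) {
    rlang::abort("mean active length is zero; CV undefined",
                 class = "streamdyn_argument_error")
  }
  sd_pop <- sqrt(mean((l - m)^2))
  tibble::tibble(
    n_days = n,
    mean_length = m,
    cv_length = sd_pop / m,
    mean_relative_length = mean(state$relative_length),
    mean_lcp_length = mean(state$lcp_length),
    min_length = min(l),
    max_length = max(l)
  )
}

#' Realized per-node persistency
#'
#' Fraction of days each node was active over a run; under the empirical
#' flow duration curve this tracks the nominal local persistency to within
#' `1/n_days`.
#'
#' @param state A `network_state_series`.
#' @return A tibble with columns `node_id`, `persistency` (nominal) and
#'   `realized` (active-day fraction).
#' @export
realized_persistency <- function(state) {
  network <- attr(state, "network")
  sp <- sort(state$p_star)
  n <- length(sp)
  active_days <- findInterval(network$persistency, sp)
  tibble::tibble(node_id = network$node_id,
                 persistency = network$persistency,
                 realized = active_days / n)
}
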