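#' Mean network persistency from climate
#'
#' Empirical linear relation between the average node persistency of a
#' temporary stream network and the catchment-scale excess precipitation:
#' `Pbar = 0.0527 + 0.1951 * (P_t - E_p)` with both terms in mm/d. The
#' relation is calibrated on observational data from temperate catchments
#' and can saturate in very arid (`Pbar <= 0`) or very humid (`Pbar >= 1`)
#' parameterisations, which raise an error by default.
#'
#' @param p_t Mean total precipitation (mm/d).
#' @param e_p Potential evapotranspiration (mm/d).
#' @param clamp If `TRUE`, values >= 1 are clamped to `1 - 1e-6` rather
#'   than raising an error.
#' @return Mean network persistency in (0, 1).
#' @examples
#' mean_network_persistency(3.75, 3.0)  # ~0.20
#' @export
mean_network_persistency <- function(p_t, e_p, clamp = FALSE) {
  pbar <- 0.0527 + 0.1951 * (p_t - e_p)
  if (any(pbar <= 0)) {
    rlang::abort("network never active under the persistency-climate relation",
                 class = "streamdyn_climate_error")
  }
  if (any(pbar >= 1)) {
    if (!clamp) {
      rlang::abort(paste0("mean persistency >= 1; the empirical relation ",
                          "saturates (use clamp = TRUE to cap at 1 - 1e-6)"),
                   class = "streamdyn_climate_error")
    }
    pbar <- pmin(pbar, 1 - 1e-6)
  }
  pbar
}

#' Beta exponent of the persistency distribution
#'
#' The one-parameter beta law of local persistency has survival function
#' `(1 - P)^beta` with `beta = 1/Pbar - 1`, so its mean is exactly `Pbar`.
#'
#' @param mean_persistency Mean network persistency in (0, 1).
#' @return The exponent `beta` (> 0).
#' @export
persistency_beta <- function(mean_persistency) {
  if (any(mean_persistency <= 0 | mean_persistency >= 1)) {
    rlang::abort("mean_persistency must lie in (0, 1)",
                 class = "streamdyn_argument_error")
  }
  1 / mean_persistency - 1
}

resolve_beta <- function(beta, mean_persistency) {
  if (is.null(beta)) {
    if (is.null(mean_persistency)) {
      rlang::abort("supply either beta or mean_persistency",
                   class = "streamdyn_argument_error")
    }
    beta <- persistency_beta(mean_persistency)
  }
  if (beta <= 0) {
    rlang::abort("beta must be > 0", class = "streamdyn_argument_error")
  }
  beta
}

#' Distribution of local persistency
#'
#' CDF and quantile function of the one-parameter beta law of local
#' persistency, `CDF(P) = 1 - (1 - P)^beta` on the temporary part of the
#' network, optionally mixed with an atom of probability at `P = 1` for
#' perennial reaches (which never dry out). With an atom of weight `f`, the
#' temporary branch carries the remaining mass `1 - f`.
#'
#' @param p Persistency value(s) in \[0, 1\].
#' @param u Probability value(s) in \[0, 1\].
#' @param mean_persistency Mean persistency of the temporary part, in (0, 1);
#'   used to compute `beta` when `beta` is not given.
#' @param beta Exponent of the beta law (> 0); overrides `mean_persistency`.
#' @param perennial_fraction Probability mass at `P = 1`, in \[0, 1).
#' @return `persistency_cdf()` returns probabilities; `persistency_quantile()`
#'   returns persistency values. The quantile function is the exact inverse
#'   of the CDF on the temporary branch:
#'   `quantile(u) = 1 - (1 - u/(1-f))^(1/beta)` for `u < 1 - f`, and 1 above.
#' @examples
#' persistency_cdf(0.5, mean_persistency = 0.5)   # uniform case
#' persistency_quantile(0.5, beta = 4)            # ~0.159
#' @export
persistency_cdf <- function(p, mean_persistency = NULL, beta = NULL,
                            perennial_fraction = 0) {
  beta <- resolve_beta(beta, mean_persistency)
  check_unit_interval(p, "p")
  check_perennial(perennial_fraction)
  out <- (1 - perennial_fraction) * (1 - (1 - p)^beta)
  out[p >= 1] <- 1
  out
}

#' @rdname persistency_cdf
#' @export
persistency_quantile <- function(u, mean_persistency = NULL, beta = NULL,
                                 perennial_fraction = 0) {
  beta <- resolve_beta(beta, mean_persistency)
  check_unit_interval(u, "u")
  check_perennial(perennial_fraction)
  f <- perennial_fraction
  ifelse(u >= 1 - f, 1, 1 - (1 - u / (1 - f))^(1 / beta))
}

check_unit_interval <- function(x, name) {
  if (any(x < 0 | x > 1)) {
    rlang::abort(paste0(name, " must lie in [0, 1]"),
                 class = "streamdyn_argument_error")
  }
  invisible(x)
}

check_perennial <- function(f) {
  if (length(f) != 1 || f < 0 || f >= 1) {
    rlang::abort("perennial_fraction must lie in [0, 1)",
                 class = "streamdyn_argument_error")
  }
  invisible(f)
}

#' Draw local persistency values
#'
#' Samples `n` node persistencies from the persistency law by inverse
#' transform, returned in ascending order. `method = "plotting_position"`
#' replaces the random uniforms by the deterministic Weibull positions
#' `i/(n+1)`, giving a variance-free discretisation of the distribution
#' (useful for tests and for exact agreement with the analytic stream
#' length duration curve).
#'
#' @param n Number of values (>= 1).
#' @inheritParams persistency_cdf
#' @param seed Integer seed (ignored for the plotting-position method).
#' @param method `"sample"` (random draws, the default) or
#'   `"plotting_position"`.
#' @return A sorted numeric vector of length `n` with values in (0, 1\].
#' @export
sample_persistency <- function(n, mean_persistency = NULL, beta = NULL,
                               perennial_fraction = 0, seed = NULL,
                               method = c("sample", "plotting_position")) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    rlang::abort("n must be a positive integer",
                 class = "streamdyn_argument_error")
  }
  method <- match.arg(method)
  beta <- resolve_beta(beta, mean_persistency)
  if (method == "sample") {
    if (!is.null(seed)) set.seed(seed)
    u <- stats::runif(n)
  } else {
    u <- seq_len(n) / (n + 1)
  }
  sort(persistency_quantile(u, beta = beta,
                            perennial_fraction = perennial_fraction))
}

#' Allocate persistency values to network nodes
#'
#' Assigns a sample of persistency values to the nodes of a geomorphic
#' network under one of three spatial arrangements sharing the same value
#' multiset:
#' \describe{
#'   \item{`random`}{a seeded uniform permutation — spatially uncorrelated
#'     persistency, the low-correlation end member;}
#'   \item{`twi`}{quantile transformation against the topographic wetness
#'     index — the i-th smallest persistency goes to the node with the i-th
#'     smallest TWI, so persistency generally (but not monotonically)
#'     increases downstream;}
#'   \item{`area`}{quantile transformation against contributing area —
#'     persistency increases systematically downstream, the maximal-
#'     correlation end member under which the active network is always
#'     connected.}
#' }
#' Ties in the covariate are broken by ascending `node_id`.
#'
#' @param network A `stream_network` with terrain attributes.
#' @param values Persistency values, one per node (typically from
#'   [sample_persistency()]; order irrelevant).
#' @param scheme Allocation scheme: `"random"`, `"twi"` or `"area"`.
#' @param seed Seed for the random scheme's permutation.
#' @return The network tibble with a `persistency` column; attributes
#'   `scheme` and `source_sample` record the arrangement and the sorted
#'   sample.
#' @export
allocate_persistency <- function(network, values,
                                 scheme = c("random", "twi", "area"),
                                 seed = NULL) {
  scheme <- match.arg(scheme)
  df <- network
  n <- nrow(df)
  if (length(values) != n) {
    rlang::abort(paste0("length(values) = ", length(values),
                        " but the network has ", n, " nodes"),
                 class = "streamdyn_argument_error")
  }
  if (any(values <= 0 | values > 1)) {
    rlang::abort("persistency values must lie in (0, 1]",
                 class = "streamdyn_argument_error")
  }
  sorted <- sort(values)
  if (scheme == "random") {
    if (!is.null(seed)) set.seed(seed)
    df$persistency <- sorted[sample.int(n)]
  } else {
    covariate <- switch(scheme, twi = df$twi, area = df$contributing_area)
    if (is.null(covariate)) {
      rlang::abort(paste0("network lacks the ", scheme, " attribute"),
                   class = "streamdyn_argument_error")
    }
    rank_cov <- order(order(covariate, df$node_id))
    df$persistency <- sorted[rank_cov]
  }
  attr(df, "scheme") <- scheme
  attr(df, "source_sample") <- sorted
  df
}

#' Read and write persistency fields
#'
#' CSV format `node_id,persistency,scheme`; reading attaches field-surveyed
#' (or previously exported) persistencies to an existing network, bypassing
#' the climate-based estimation entirely.
#'
#' @param network A `stream_network`.
#' @param path CSV path.
#' @return `read_persistency_field()` returns the network with the
#'   persistency column attached; `write_persistency_field()` returns
#'   `path` invisibly.
#' @export
write_persistency_field <- function(network, path) {
  if (!"persistency" %in% names(network)) {
    rlang::abort("network carries no persistency field",
                 class = "streamdyn_argument_error")
  }
  scheme <- attr(network, "scheme") %||% "custom"
  readr::write_csv(tibble::tibble(node_id = network$node_id,
                                  persistency = network$persistency,
                                  scheme = scheme), path)
  invisible(path)
}

#' @rdname write_persistency_field
#' @export
read_persistency_field <- function(network, path) {
  fld <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           node_id = readr::col_integer(),
                           persistency = readr::col_double(),
                           .default = readr::col_character()))
  idx <- match(network$node_id, fld$node_id)
  if (anyNA(idx)) {
    rlang::abort("persistency file does not cover all network nodes",
                 class = "streamdyn_format_error")
  }
  network$persistency <- fld$persistency[idx]
  attr(network, "scheme") <- if (length(unique(fld$scheme)) == 1)
    fld$scheme[1] else "custom"
  attr(network, "source_sample") <- sort(network$persistency)
  network
}
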