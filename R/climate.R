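#' Climatic scenarios
#'
#' A climate scenario bundles the four independent hydroclimatic parameters
#' of the framework: mean daily rainfall depth `alpha` (mm/d), rainfall
#' frequency `lambda_p` (1/d), potential evapotranspiration `e_p` (mm/d) and
#' the streamflow recession rate `k` (1/d).
#'
#' @param label Short scenario name (e.g. `"D"`, `"W"`).
#' @param alpha Mean daily rainfall depth (mm/d), > 0.
#' @param lambda_p Rainfall frequency (1/d), > 0.
#' @param e_p Potential evapotranspiration (mm/d), >= 0.
#' @param k Recession rate (1/d), > 0. Default 0.35.
#' @return A one-row tibble of class `climate_scenario`.
#' @examples
#' climate_scenario("D", alpha = 15, lambda_p = 0.25, e_p = 3)
#' @export
climate_scenario <- function(label, alpha, lambda_p, e_p, k = 0.35) {
  stopifnot(length(alpha) == 1, length(lambda_p) == 1,
            length(e_p) == 1, length(k) == 1)
  if (alpha <= 0 || lambda_p <= 0 || e_p < 0 || k <= 0) {
    rlang::abort(
      "require alpha > 0, lambda_p > 0, e_p >= 0, k > 0",
      class = "streamdyn_argument_error")
  }
  out <- tibble::tibble(label = as.character(label), alpha = alpha,
                        lambda_p = lambda_p, e_p = e_p, k = k)
  class(out) <- c("climate_scenario", class(out))
  out
}

#' Actual evapotranspiration from the Budyko curve
#'
#' Partitions mean total precipitation into actual evapotranspiration using
#' the Budyko relation
#' `E_a / P_t = sqrt( (E_p/P_t) * tanh(P_t/E_p) * (1 - exp(-E_p/P_t)) )`.
#'
#' @param p_t Mean total precipitation (mm/d), > 0. Vectorised.
#' @param e_p Potential evapotranspiration (mm/d), >= 0. Vectorised.
#' @return Actual evapotranspiration `E_a` (mm/d), bounded by
#'   `min(p_t, e_p)` and equal to 0 when `e_p = 0`.
#' @examples
#' budyko_actual_et(3.75, 3.0)  # 2.29 mm/d
#' @export
budyko_actual_et <- function(p_t, e_p) {
  if (any(p_t <= 0)) {
    rlang::abort("p_t must be > 0", class = "streamdyn_argument_error")
  }
  if (any(e_p < 0)) {
    rlang::abort("e_p must be >= 0", class = "streamdyn_argument_error")
  }
  ratio <- e_p / p_t
  ifelse(e_p == 0, 0,
         p_t * sqrt(ratio * tanh(1 / ratio) * (1 - exp(-ratio))))
}

#' Effective rainfall frequency from the catchment water balance
#'
#' Only rain events that fill the soil-moisture deficit left by
#' evapotranspiration reach the stream; Poisson thinning of the rainfall
#' process gives the effective frequency `lambda = lambda_p - e_a / alpha`,
#' so that the mean effective precipitation `alpha * lambda` equals
#' `P_t - E_a`.
#'
#' @param lambda_p Rainfall frequency (1/d).
#' @param e_a Actual evapotranspiration (mm/d).
#' @param alpha Mean daily rainfall depth (mm/d), > 0.
#' @return Effective rainfall frequency (1/d), > 0.
#' @examples
#' effective_rainfall_frequency(0.25, budyko_actual_et(3.75, 3.0), 15)
#' @export
effective_rainfall_frequency <- function(lambda_p, e_a, alpha) {
  if (any(alpha <= 0)) {
    rlang::abort("alpha must be > 0", class = "streamdyn_argument_error")
  }
  lambda <- lambda_p - e_a / alpha
  if (any(lambda <= 0)) {
    rlang::abort("no effective rainfall (hyper-arid parameterization)",
                 class = "streamdyn_climate_error")
  }
  lambda
}

#' Derive the full parameter set of a climate scenario
#'
#' Chains, at full numerical precision, the mean total precipitation
#' `P_t = alpha * lambda_p`, the Budyko actual evapotranspiration, the
#' effective rainfall frequency and the mean network persistency
#' `Pbar = 0.0527 + 0.1951 * (P_t - E_p)`, and the derived beta exponent of
#' the persistency distribution.
#'
#' @param scenario A [climate_scenario()] (or a one-row data frame with the
#'   same columns).
#' @param clamp_persistency If `TRUE`, mean persistencies >= 1 (very humid
#'   parameterisations for which the empirical persistency relation
#'   saturates) are clamped to `1 - 1e-6` instead of raising an error.
#' @return A one-row tibble with the scenario columns plus `p_t`, `e_a`,
#'   `lambda_eff`, `ratio_lambda_k`, `mean_persistency` and `beta`.
#' @examples
#' derive_climate(climate_scenario("D", 15, 0.25, 3))
#' @export
derive_climate <- function(scenario, clamp_persistency = FALSE) {
  sc <- tibble::as_tibble(scenario)
  p_t <- sc$alpha * sc$lambda_p
  e_a <- budyko_actual_et(p_t, sc$e_p)
  lambda_eff <- effective_rainfall_frequency(sc$lambda_p, e_a, sc$alpha)
  pbar <- mean_network_persistency(p_t, sc$e_p, clamp = clamp_persistency)
  dplyr::mutate(sc,
                p_t = p_t,
                e_a = e_a,
                lambda_eff = lambda_eff,
                ratio_lambda_k = lambda_eff / sc$k,
                mean_persistency = pbar,
                beta = persistency_beta(pbar))
}

#' Bundled climatic presets
#'
#' The two contrasting scenarios used throughout the package: `"D"` (dry:
#' sparse, intense rainfall and high evaporative demand, erratic flow
#' regime) and `"W"` (wet: frequent rainfall and moderate demand, persistent
#' flow regime). The recession rate is 0.35 1/d in both.
#'
#' @param label Optional, `"D"` or `"W"`, to select a single preset.
#' @return A `climate_scenario` tibble (two rows if `label` is `NULL`).
#' @export
climate_presets <- function(label = NULL) {
  presets <- dplyr::bind_rows(
    climate_scenario("D", alpha = 15.0, lambda_p = 0.25, e_p = 3.0, k = 0.35),
    climate_scenario("W", alpha = 10.0, lambda_p = 0.55, e_p = 2.0, k = 0.35))
  class(presets) <- c("climate_scenario", class(tibble::tibble()))
  if (!is.null(label)) {
    label <- toupper(label)
    if (!label %in% presets$label) {
      rlang::abort(paste0("unknown climate preset: ", label),
                   class = "streamdyn_argument_error")
    }
    presets <- presets[presets$label == label, ]
  }
  presets
}

#' Preset table with derived parameters
#'
#' Convenience wrapper returning both climate presets with all derived
#' quantities (`P_t`, `E_a`, `lambda`, `lambda/k`, mean persistency, beta)
#' computed at full precision.
#'
#' @return A two-row tibble.
#' @examples
#' preset_table()
#' @export
preset_table <- function() {
  dplyr::bind_rows(lapply(c("D", "W"), function(l) {
    derive_climate(climate_presets(l))
  }))
}
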