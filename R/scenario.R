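scheme_codes <- c("1" = "random", "2" = "twi", "3" = "area")

#' Resolve a two-digit scenario label
#'
#' Labels combine a climate letter (`D` dry, `W` wet) with an allocation
#' digit (1 random, 2 TWI, 3 contributing area); e.g. `"W3"` is the wet
#' climate with persistency increasing with contributing area.
#'
#' @param label One of `"D1"`, `"D2"`, `"D3"`, `"W1"`, `"W2"`, `"W3"`.
#' @return A list with elements `climate` (a `climate_scenario`) and
#'   `scheme` (allocation scheme name).
#' @export
resolve_scenario_label <- function(label) {
  label <- toupper(label)
  if (!grepl("^[DW][123]$", label)) {
    rlang::abort(paste0("unknown scenario label: ", label,
                        " (expected D1..D3 or W1..W3)"),
                 class = "streamdyn_argument_error")
  }
  list(climate = climate_presets(substr(label, 1, 1)),
       scheme = unname(scheme_codes[substr(label, 2, 2)]))
}

#' Configuration of a simulation run
#'
#' Collects everything a run needs: the climate (preset label or a custom
#' [climate_scenario()]), the persistency allocation scheme, run length,
#' network size, and four independent seeds (network topology, persistency
#' sample, allocation permutation, streamflow) so that e.g. D1/D2/D3 can
#' share the same network and persistency sample while varying only the
#' spatial arrangement. Sub-seeds default to deterministic offsets of
#' `seed`.
#'
#' @param scenario Two-digit label (`"D1"`..`"W3"`) or `"custom"`.
#' @param climate A `climate_scenario`; required when `scenario = "custom"`.
#' @param scheme Allocation scheme; required when `scenario = "custom"`.
#' @param n_years Run length in years of 365 days (default 100).
#' @param n_nodes Network size (default 1215).
#' @param seed Master seed from which unset sub-seeds are derived.
#' @param seed_network,seed_sample,seed_allocation,seed_flow Optional
#'   per-stage seeds overriding the derived defaults.
#' @param fdc_mode `"empirical"` (default) or `"analytic"` flow duration
#'   curve in the threshold transformation.
#' @param network Optional pre-built `stream_network` to use instead of a
#'   synthetic one.
#' @return A list of class `run_config`.
#' @export
run_config <- function(scenario = "W2", climate = NULL, scheme = NULL,
                       n_years = 100, n_nodes = 1215, seed = 1L,
                       seed_network = NULL, seed_sample = NULL,
                       seed_allocation = NULL, seed_flow = NULL,
                       fdc_mode = c("empirical", "analytic"),
                       network = NULL) {
  fdc_mode <- match.arg(fdc_mode)
  if (n_years < 1) {
    rlang::abort("n_years must be >= 1", class = "streamdyn_argument_error")
  }
  if (identical(scenario, "custom")) {
    if (is.null(climate) || is.null(scheme)) {
      rlang::abort("custom scenarios need climate and scheme",
                   class = "streamdyn_argument_error")
    }
  } else {
    resolved <- resolve_scenario_label(scenario)
    if (!is.null(scheme) && !identical(scheme, resolved$scheme)) {
      rlang::abort(paste0("scheme \"", scheme, "\" contradicts label ",
                          scenario), class = "streamdyn_argument_error")
    }
    climate <- climate %||% resolved$climate
    scheme <- resolved$scheme
  }
  seed <- as.integer(seed)
  structure(list(
    scenario = scenario,
    climate = climate,
    scheme = scheme,
    n_years = n_years,
    n_nodes = as.integer(n_nodes),
    seed = seed,
    seed_network = as.integer(seed_network %||% (seed + 101L)),
    seed_sample = as.integer(seed_sample %||% (seed + 202L)),
    seed_allocation = as.integer(seed_allocation %||% (seed + 303L)),
    seed_flow = as.integer(seed_flow %||% (seed + 404L)),
    fdc_mode = fdc_mode,
    network = network
  ), class = "run_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(paste0("stage \"", stage, "\" failed: ", conditionMessage(e)),
                 class = "streamdyn_run_error", parent = e)
  })
}

#' Run a full network-dynamics scenario
#'
#' Orchestrates the whole pipeline: derive the climate parameters, build
#' (or take) the geomorphic network, sample and allocate local
#' persistencies, simulate daily streamflow, convert it to persistency
#' thresholds and node states, and assemble duration and connectivity
#' curves with summary statistics. Identical configuration and seeds give
#' bit-identical results (and byte-identical exported files).
#'
#' @param config A [run_config()]; alternatively pass a scenario label and
#'   `...` arguments forwarded to [run_config()].
#' @param q_series Optional externally supplied discharge tibble
#'   (`day`, `q`), e.g. observations, replacing the stochastic streamflow
#'   stage; downstream behaviour is unchanged.
#' @param out_dir Optional directory: if given, all standard exports are
#'   written there (see [write_run()]).
#' @param ... Forwarded to [run_config()] when `config` is a label.
#' @return A list of class `streamdyn_run` with elements `config`,
#'   `climate` (derived parameter tibble), `network` (with persistency),
#'   `flow`, `state` (daily series), `fdc`, `sldc`, `lcp`, `summary`.
#' @examples
#' run <- run_scenario("W1", n_years = 2, n_nodes = 100, seed = 7)
#' glance(run)
#' @export
run_scenario <- function(config, q_series = NULL, out_dir = NULL, ...) {
  if (!inherits(config, "run_config")) {
    config <- run_config(scenario = config, ...)
  }
  climate <- run_stage("climate", derive_climate(config$climate))
  network <- run_stage("network", {
    if (is.null(config$network)) {
      generate_network(config$n_nodes, seed = config$seed_network)
    } else {
      as_stream_network(config$network)
    }
  })
  field <- run_stage("persistency", {
    values <- sample_persistency(nrow(network),
                                 mean_persistency = climate$mean_persistency,
                                 seed = config$seed_sample)
    allocate_persistency(network, values, scheme = config$scheme,
                         seed = config$seed_allocation)
  })
  n_days <- config$n_years * 365L
  flow <- run_stage("streamflow", {
    if (is.null(q_series)) {
      simulate_streamflow(climate$alpha, climate$lambda_eff, climate$k,
                          n_days = n_days, seed = config$seed_flow)
    } else {
      out <- tibble::as_tibble(q_series)
      attr(out, "params") <- list(alpha = climate$alpha,
                                  lambda = climate$lambda_eff,
                                  k = climate$k)
      out
    }
  })
  state <- run_stage("dynamics", {
    simulate_network_dynamics(field, flow, fdc_mode = config$fdc_mode,
                              alpha = climate$alpha,
                              lambda = climate$lambda_eff, k = climate$k)
  })
  fdc <- run_stage("fdc", empirical_fdc(flow))
  sldc_emp <- run_stage("sldc", {
    dc <- duration_curve(state$relative_length)
    dplyr::rename(dc, relative_length = "value")
  })
  lcp <- run_stage("lcp", lcp_curve(field))
  summary <- run_stage("summary", summarize_dynamics(state))
  run <- structure(list(
    config = config,
    climate = climate,
    network = field,
    flow = flow,
    state = state,
    fdc = fdc,
    sldc = sldc_emp,
    lcp = lcp,
    summary = summary
  ), class = "streamdyn_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Export a run to a directory
#'
#' Writes `timeseries.csv` (day, q, p_star, n_active, active_length,
#' relative_length, lcp_length), `fdc.csv`, `sldc.csv`, `lcp_curve.csv`,
#' `nodes.csv` (network plus persistency) and `manifest.yml` (the resolved
#' configuration with all derived parameters). On any failure, partially
#' written files are removed.
#'
#' @param run A `streamdyn_run`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(out_dir, c("timeseries.csv", "fdc.csv", "sldc.csv",
                                "lcp_curve.csv", "nodes.csv", "manifest.yml"))
  tryCatch({
    readr::write_csv(tibble::as_tibble(run$state), files[1])
    readr::write_csv(tibble::as_tibble(run$fdc), files[2])
    readr::write_csv(run$sldc, files[3])
    readr::write_csv(run$lcp, files[4])
    readr::write_csv(tibble::as_tibble(run$network), files[5])
    cfg <- run$config
    manifest <- list(
      scenario = cfg$scenario,
      scheme = cfg$scheme,
      n_years = cfg$n_years,
      n_nodes = cfg$n_nodes,
      fdc_mode = cfg$fdc_mode,
      seeds = list(network = cfg$seed_network, sample = cfg$seed_sample,
                   allocation = cfg$seed_allocation, flow = cfg$seed_flow),
      climate = as.list(run$climate)
    )
    yaml::write_yaml(manifest, files[6])
  }, error = function(e) {
    unlink(files)
    rlang::abort(paste0("export failed: ", conditionMessage(e)),
                 class = "streamdyn_run_error", parent = e)
  })
  invisible(out_dir)
}

#' @export
print.streamdyn_run <- function(x, ...) {
  s <- x$summary
  cat("<streamdyn_run> scenario", x$config$scenario,
      sprintf("(%s climate, %s allocation)\n",
              x$climate$label, x$config$scheme))
  cat(sprintf("  %d nodes, %d days, fdc_mode = %s\n",
              nrow(x$network), s$n_days, x$config$fdc_mode))
  cat(sprintf("  mean relative length %.3f, CV of active length %.3f\n",
              s$mean_relative_length, s$cv_length))
  invisible(x)
}

#' Tidy the daily state series of a run
#'
#' @param x A `streamdyn_run`.
#' @param ... Unused.
#' @return The daily tibble (`day`, `q`, `p_star`, `n_active`,
#'   `active_length`, `relative_length`, `lcp_length`).
#' @method tidy streamdyn_run
#' @export
tidy.streamdyn_run <- function(x, ...) {
  tibble::as_tibble(x$state)
}

#' One-row summary of a run
#'
#' @param x A `streamdyn_run`.
#' @param ... Unused.
#' @return A one-row tibble: scenario, scheme, derived climate parameters
#'   (`p_t`, `e_a`, `lambda_eff`, `mean_persistency`, `beta`) and the
#'   active-length statistics of [summarize_dynamics()].
#' @method glance streamdyn_run
#' @export
glance.streamdyn_run <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(scenario = x$config$scenario, scheme = x$config$scheme),
    dplyr::select(x$climate, "p_t", "e_a", "lambda_eff",
                  "mean_persistency", "beta"),
    x$summary
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
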