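test_that("empirical thresholds are Weibull exceedance positions", {
  s <- tibble::tibble(day = 1:5, q = c(2, 9, 4, 1, 7))
  thr <- persistency_threshold(s, fdc_mode = "empirical")
  # day with the maximum discharge gets rank 1
  expect_equal(thr$p_star[2], 1 / 6)
  expect_equal(thr$p_star, c(4, 1, 3, 5, 2) / 6)
  # higher discharge, lower threshold
  expect_equal(order(thr$q), order(thr$p_star, decreasing = TRUE))
})

test_that("analytic threshold of zero flow is full contraction", {
  s <- tibble::tibble(day = 1:2, q = c(0, 5))
  thr <- persistency_threshold(s, fdc_mode = "analytic",
                               alpha = 10, lambda = 0.37, k = 0.35)
  expect_equal(thr$p_star[1], 1)
  expect_lt(thr$p_star[2], 1)
})

test_that("analytic thresholds are uniformly distributed (probability integral transform)", {
  s <- simulate_streamflow(10, 0.3676, 0.35, n_days = 36500, seed = 55)
  thr <- persistency_threshold(s, fdc_mode = "analytic")
  p <- sort(thr$p_star)
  n <- length(p)
  ks <- max(pmax(abs(seq_len(n) / n - p), abs((seq_len(n) - 1) / n - p)))
  expect_lt(ks, 0.02)
})

test_that("node states switch on the inclusive persistency threshold", {
  p <- c(0.2, 0.5, 0.8)
  expect_equal(node_status(p, 0.1), c(1L, 1L, 1L))
  expect_equal(node_status(p, 0.9), c(0L, 0L, 0L))
  # equality activates the node
  expect_equal(node_status(p, 0.5), c(0L, 1L, 1L))
  expect_error(node_status(p, 0), class = "streamdyn_argument_error")
})

test_that("active length sums reach lengths of active nodes", {
  net <- chain_network(4)
  expect_equal(active_length(rep(1L, 4), net), geomorphic_length(net))
  expect_equal(active_length(rep(0L, 4), net), 0)
  expect_equal(active_length(c(1L, 0L, 1L, 1L), net), 3)
  expect_error(active_length(c(1L, 0L), net),
               class = "streamdyn_argument_error")
})

test_that("analytic SLDC matches its closed form and published quantiles", {
  wet <- derive_climate(climate_presets("W"))
  dry <- derive_climate(climate_presets("D"))
  # ~93% of the wet network active at least 20% of the time
  expect_lt(abs(100 * sldc_analytic(0.2, beta = wet$beta) - 93), 1)
  expect_equal(sldc_analytic(0, beta = 2), 1)
  expect_equal(sldc_analytic(1, beta = 2), 0)
  # half-network duration: closed-form inversion
  expect_equal(sldc_inverse(0.5, beta = dry$beta),
               1 - 0.5^(1 / dry$beta), tolerance = 1e-14)
  expect_lte(sldc_inverse(0.5, beta = dry$beta), 0.2)
  expect_gte(sldc_inverse(0.5, beta = wet$beta), 0.8)
  # inverse really inverts
  d <- seq(0.05, 0.95, by = 0.05)
  expect_equal(sldc_inverse(sldc_analytic(d, beta = 4), beta = 4), d,
               tolerance = 1e-12)
  # strictly decreasing in duration
  expect_true(all(diff(sldc_analytic(d, beta = 0.36)) < 0))
  expect_error(sldc_analytic(1.5, beta = 1),
               class = "streamdyn_argument_error")
})

test_that("empirical duration curves rank any daily quantity", {
  dc <- duration_curve(c(10, 30, 20))
  expect_equal(dc$value, c(30, 20, 10))
  expect_equal(dc$duration, c(0.25, 0.5, 0.75))
  const <- duration_curve(rep(7, 9))
  expect_equal(unique(const$duration), 9 / 10)
  expect_error(duration_curve(numeric(0)), class = "streamdyn_argument_error")
})

test_that("simulated SLDC converges to the sample-persistency curve", {
  run <- cached_run("W1")
  net <- run$network
  n_nodes <- nrow(net)
  # expected relative length at duration D: fraction of nodes with P_i >= D
  emp <- run$sldc
  expected <- vapply(emp$duration,
                     function(d) sum(net$persistency >= d) / n_nodes,
                     numeric(1))
  expect_lt(max(abs(emp$relative_length - expected)), 0.02)
})

test_that("largest connected patch matches brute-force enumeration", {
  skip_if_not_installed("igraph")
  # frozen toy example: active {A, C, D} -> components {A} and {C, D}
  net <- toy_y_tree()
  curve <- lcp_curve(net, p_star_grid = 0.5)
  expect_equal(curve$active_length, 3)
  expect_equal(curve$lcp_length, 2)
  expect_equal(lcp_brute_force(net, 0.5), 2)
  # whole tree is one component below the minimum persistency
  expect_equal(lcp_curve(net, p_star_grid = 0.1)$lcp_length,
               geomorphic_length(net))
  # randomised cross-check across networks and schemes
  for (seed in 1:3) {
    nn <- generate_network(60, seed = seed)
    vals <- sample_persistency(60, mean_persistency = 0.4, seed = seed + 50)
    for (scheme in c("random", "twi", "area")) {
      fld <- allocate_persistency(nn, vals, scheme = scheme, seed = seed)
      grid <- seq(0.05, 0.95, by = 0.1)
      ours <- lcp_curve(fld, p_star_grid = grid)
      oracle <- vapply(grid, function(p) lcp_brute_force(fld, p), numeric(1))
      expect_equal(ours$lcp_length, oracle)
    }
  }
})

test_that("area allocation keeps the active network fully connected", {
  net <- generate_network(400, seed = 8)
  vals <- sample_persistency(400, mean_persistency = 0.3, seed = 9)
  fld <- allocate_persistency(net, vals, scheme = "area")
  curve <- lcp_curve(fld, p_star_grid = seq(0.01, 1, by = 0.01))
  expect_equal(curve$lcp_length, curve$active_length)
})

test_that("LCP never exceeds the active length", {
  run <- cached_run("D1")
  expect_true(all(run$state$lcp_length <= run$state$active_length))
  expect_true(all(run$lcp$lcp_length <= run$lcp$active_length))
})

test_that("configurations are nested and in bijection with active length", {
  net <- generate_network(80, seed = 30)
  vals <- sample_persistency(80, mean_persistency = 0.4, seed = 31)
  fld <- allocate_persistency(net, vals, scheme = "random", seed = 32)
  flow <- simulate_streamflow(15, 0.0972, 0.35, n_days = 400, seed = 33)
  state <- simulate_network_dynamics(fld, flow)
  # nestedness: lower threshold implies a superset configuration
  days <- seq(1, 400, by = 7)
  status <- lapply(state$p_star[days], function(p) node_status(fld, p))
  ord <- order(state$p_star[days])
  for (i in seq_along(ord)[-1]) {
    sup <- status[[ord[i - 1]]]  # lower threshold: more expanded
    sub <- status[[ord[i]]]
    expect_true(all(sup >= sub))
  }
  # bijectivity: equal lengths imply identical configurations
  expect_equal(state$active_length, state$n_active * 1)
  expect_true(all(state$active_length ==
                    vapply(state$p_star, function(p)
                      active_length(node_status(fld, p), fld), numeric(1))))
})

test_that("realized node persistency tracks the nominal value", {
  run <- cached_run("W1")
  rp <- realized_persistency(run$state)
  n <- nrow(run$state)
  # exact discretisation under the empirical FDC (no ties in Q)
  expect_equal(rp$realized, floor(rp$persistency * (n + 1)) / n,
               tolerance = 1e-12)
  expect_lte(max(abs(rp$realized - rp$persistency)), 1 / n + 1e-9)
})

test_that("long-run mean relative length converges to the mean persistency", {
  for (label in c("D1", "W1")) {
    run <- cached_run(label)
    pbar <- run$climate$mean_persistency
    b <- run$climate$beta
    v <- b / ((1 + b)^2 * (2 + b))  # Beta(1, beta) variance
    se <- sqrt(v / nrow(run$network))
    expect_lt(abs(run$summary$mean_relative_length - pbar), 3 * se + 1e-3)
  }
})

test_that("active-length variability matches the closed-form coefficient of variation", {
  # validate the closed form sqrt(beta^2 / (2 beta + 1)) by quadrature:
  # L/Lg | P* = (1 - P*)^beta with P* uniform, so moments are integrals of
  # u^beta and u^(2 beta)
  for (b in c(0.35952, 1, 4.02449)) {
    m1 <- stats::integrate(function(u) u^b, 0, 1, rel.tol = 1e-12)$value
    m2 <- stats::integrate(function(u) u^(2 * b), 0, 1, rel.tol = 1e-12)$value
    cv_quad <- sqrt(m2 - m1^2) / m1
    expect_equal(cv_quad, sqrt(b^2 / (2 * b + 1)), tolerance = 1e-9)
  }
  # the simulated CV brackets the oracle
  for (label in c("D1", "W1")) {
    run <- cached_run(label)
    b <- run$climate$beta
    oracle <- sqrt(b^2 / (2 * b + 1))
    expect_equal(run$summary$cv_length, oracle, tolerance = 0.08)
  }
})

test_that("dynamics summaries handle degenerate series", {
  state <- tibble::tibble(day = 1:10, q = 1, p_star = 0.5,
                          n_active = 5L, active_length = 5,
                          relative_length = 0.5, lcp_length = 5)
  class(state) <- c("network_state_series", class(state))
  s <- summarize_dynamics(state)
  expect_equal(s$cv_length, 0)
  zero <- dplyr::mutate(state, active_length = 0, relative_length = 0)
  expect_error(summarize_dynamics(zero), class = "streamdyn_argument_error")
  expect_error(summarize_dynamics(state[1, ]),
               class = "streamdyn_argument_error")
})
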