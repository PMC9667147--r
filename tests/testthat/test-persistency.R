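test_that("mean network persistency follows the empirical climate relation", {
  expect_equal(round(mean_network_persistency(3.75, 3.0), 2), 0.20)
  expect_equal(round(mean_network_persistency(5.50, 2.0), 2), 0.74)
  expect_equal(mean_network_persistency(3.75, 3.0),
               0.0527 + 0.1951 * 0.75, tolerance = 1e-14)
})

test_that("the climate relation saturates outside (0, 1)", {
  # solve 0.0527 + 0.1951 * x = 1 for the saturation boundary
  x1 <- (1 - 0.0527) / 0.1951
  expect_error(mean_network_persistency(x1 + 0.01, 0),
               class = "streamdyn_climate_error")
  expect_equal(mean_network_persistency(x1 + 0.01, 0, clamp = TRUE),
               1 - 1e-6)
  # arid limit: relation drops to zero and below
  expect_error(mean_network_persistency(1, 2),
               class = "streamdyn_climate_error")
})

test_that("persistency CDF and quantile are exact inverses", {
  # beta = 1 (mean 0.5) reduces to the uniform distribution
  expect_equal(persistency_cdf(0.5, mean_persistency = 0.5), 0.5)
  expect_equal(persistency_cdf(0, beta = 3), 0)
  expect_equal(persistency_cdf(1, beta = 3), 1)
  # closed-form inversion
  expect_equal(persistency_quantile(0.5, beta = 4), 1 - 0.5^(1 / 4))
  expect_equal(persistency_quantile(0.5, beta = 4), 0.1591, tolerance = 1e-4)
  u <- seq(0.01, 0.99, by = 0.01)
  for (b in c(0.36, 1, 4.02)) {
    expect_equal(persistency_cdf(persistency_quantile(u, beta = b), beta = b),
                 u, tolerance = 1e-12)
  }
  expect_error(persistency_cdf(1.2, beta = 1),
               class = "streamdyn_argument_error")
  expect_error(persistency_quantile(-0.1, beta = 1),
               class = "streamdyn_argument_error")
})

test_that("the distribution mean equals the prescribed network persistency", {
  # oracle: numerical integration of the survival function
  for (pbar in c(0.2, 0.5, 0.74)) {
    b <- persistency_beta(pbar)
    m <- stats::integrate(function(p) 1 - persistency_cdf(p, beta = b),
                          0, 1, rel.tol = 1e-12)$value
    expect_equal(m, pbar, tolerance = 1e-9)
  }
})

test_that("perennial atom is honoured by CDF, quantile and sampling", {
  f <- 0.3
  expect_equal(persistency_quantile(0.8, beta = 2, perennial_fraction = f), 1)
  expect_lt(persistency_quantile(0.69, beta = 2, perennial_fraction = f), 1)
  expect_equal(persistency_cdf(1, beta = 2, perennial_fraction = f), 1)
  s <- sample_persistency(1e4, beta = 2, perennial_fraction = f, seed = 31)
  frac <- mean(s == 1)
  expect_lt(abs(frac - f), 3 * sqrt(f * (1 - f) / 1e4))
})

test_that("sampling recovers the persistency distribution", {
  pbar <- 0.2
  s <- sample_persistency(1e5, mean_persistency = pbar, seed = 17)
  expect_true(all(diff(s) >= 0))
  # standard error from the Beta(1, beta) variance
  b <- persistency_beta(pbar)
  v <- b / ((1 + b)^2 * (2 + b))
  expect_lt(abs(mean(s) - pbar), 3 * sqrt(v / 1e5))
  # distributional recovery: KS distance against the closed-form CDF
  n <- length(s)
  theo <- persistency_cdf(s, beta = b)
  ks <- max(pmax(abs(seq_len(n) / n - theo), abs((seq_len(n) - 1) / n - theo)))
  expect_lt(ks, 0.01)
  # determinism
  expect_identical(s, sample_persistency(1e5, mean_persistency = pbar,
                                         seed = 17))
})

test_that("plotting-position sampling is the deterministic discretisation", {
  s <- sample_persistency(99, beta = 4, method = "plotting_position")
  expect_equal(s, persistency_quantile((1:99) / 100, beta = 4))
})

test_that("allocation permutes but never alters the value multiset", {
  net <- generate_network(200, seed = 4)
  vals <- sample_persistency(200, mean_persistency = 0.3, seed = 5)
  for (scheme in c("random", "twi", "area")) {
    fld <- allocate_persistency(net, vals, scheme = scheme, seed = 6)
    expect_equal(sort(fld$persistency), sort(vals))
    expect_equal(attr(fld, "scheme"), scheme)
  }
  expect_error(allocate_persistency(net, vals[-1], scheme = "random"),
               class = "streamdyn_argument_error")
})

test_that("area allocation makes persistency non-decreasing downstream", {
  net <- generate_network(300, seed = 9)
  vals <- sample_persistency(300, mean_persistency = 0.5, seed = 10)
  fld <- allocate_persistency(net, vals, scheme = "area")
  ds <- match(fld$downstream_id, fld$node_id)
  has_ds <- !is.na(ds)
  expect_true(all(fld$persistency[ds[has_ds]] >= fld$persistency[has_ds]))
})

test_that("quantile transformation preserves covariate order", {
  net <- generate_network(150, seed = 12)
  vals <- sample_persistency(150, mean_persistency = 0.4, seed = 13)
  for (scheme in c("twi", "area")) {
    fld <- allocate_persistency(net, vals, scheme = scheme)
    cov <- if (scheme == "twi") fld$twi else fld$contributing_area
    ord <- order(cov, fld$node_id)
    expect_true(all(diff(fld$persistency[ord]) >= 0))
  }
})

test_that("random allocation is uncorrelated with contributing area", {
  net <- generate_network(1215, seed = 14)
  vals <- sample_persistency(1215, mean_persistency = 0.2, seed = 15)
  fld <- allocate_persistency(net, vals, scheme = "random", seed = 16)
  rho <- stats::cor(fld$persistency, fld$contributing_area,
                    method = "spearman")
  # null 99% band for independence from the permutation distribution
  set.seed(99)
  null_rho <- replicate(2000, stats::cor(sample(fld$persistency),
                                         fld$contributing_area,
                                         method = "spearman"))
  band <- stats::quantile(null_rho, c(0.005, 0.995))
  expect_gt(rho, band[1])
  expect_lt(rho, band[2])
})

test_that("persistency fields round-trip through CSV export", {
  net <- generate_network(40, seed = 20)
  vals <- sample_persistency(40, mean_persistency = 0.6, seed = 21)
  fld <- allocate_persistency(net, vals, scheme = "twi")
  path <- withr::local_tempfile(fileext = ".csv")
  write_persistency_field(fld, path)
  back <- read_persistency_field(net, path)
  expect_equal(back$persistency, fld$persistency)
  expect_equal(attr(back, "scheme"), "twi")
})
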