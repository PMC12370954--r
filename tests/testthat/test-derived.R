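test_that("self-thinning line closed forms match published arithmetic", {
  s <- stl_from_params(-29.61, 2.95, 2.40)
  expect_equal(s$intercept, 12.5451, tolerance = 1e-4)
  expect_equal(s$slope, -1.645833, tolerance = 1e-6)
  s2 <- stl_from_params(-29.38, 2.92, 2.38)
  expect_equal(s2$intercept, 12.5542, tolerance = 1e-4)
  expect_equal(s2$slope, -1.647059, tolerance = 1e-6)
  s3 <- stl_from_params(0, 0, 1)
  expect_equal(s3$intercept, 0)
  expect_equal(s3$slope, -1)
  expect_error(stl_from_params(-29, 2.9, -1), "beta2")
  expect_error(stl_from_params(-29, -1.5, 2.4), "beta1")
})

test_that("the line is the stationary trajectory of the mortality model", {
  # on log N = intercept + slope log D, the local trajectory slope
  # -exp(b0 + b1 log D + b2 log N) * D equals the line slope at any D
  for (b in list(c(-29.61, 2.95, 2.40), c(-29.38, 2.92, 2.38),
                 c(-20, 1.5, 1.8))) {
    s <- stl_from_params(b[1], b[2], b[3])
    d <- exp(seq(log(5), log(150), length.out = 20))
    logN <- s$intercept + s$slope * log(d)
    traj_slope <- -exp(b[1] + b[2] * log(d) + b[3] * logN) * d
    expect_equal(traj_slope, rep(s$slope, 20), tolerance = 1e-10)
  }
})

test_that("climate effect sizes and capacity multipliers are exact", {
  expect_equal(intercept_effect(0.22, 2.40), -0.0916667, tolerance = 1e-6)
  expect_equal(intercept_effect(0.28, 2.38), -0.1176471, tolerance = 1e-6)
  expect_equal(intercept_effect(0, 5), 0)
  expect_equal(capacity_multiplier(-0.09, 1), 0.9139, tolerance = 1e-4)
  expect_equal(capacity_multiplier(-0.09, 3), 0.7634, tolerance = 1e-4)
  expect_equal(capacity_multiplier(-0.4, 0), 1)
  # exponential additivity in the temperature shift
  set.seed(2)
  for (i in 1:20) {
    e <- runif(1, -0.3, 0.1); a <- runif(1, 0, 4); b <- runif(1, 0, 4)
    expect_equal(capacity_multiplier(e, a + b),
                 capacity_multiplier(e, a) * capacity_multiplier(e, b),
                 tolerance = 1e-12)
  }
})

test_that("draw-wise propagation matches closed forms and brute force", {
  set.seed(5)
  dr <- data.frame(x = rnorm(20000))
  # identity reproduces the input summary
  id <- propagate(dr, function(d) d$x)
  expect_equal(id$mean, mean(dr$x))
  expect_equal(id$lower, quantile(dr$x, 0.025, names = FALSE))
  # lognormal closed form
  ex <- propagate(dr, function(d) exp(d$x))
  expect_equal(ex$mean, exp(0.5), tolerance = 0.05)
  expect_equal(ex$lower, exp(-1.96), tolerance = 0.1)
  expect_equal(ex$upper, exp(1.96), tolerance = 0.1)
  # quantiles equal an independent pass over the same draws
  v <- exp(dr$x)
  expect_identical(ex$lower, quantile(v, 0.025, names = FALSE))
  expect_identical(ex$upper, quantile(v, 0.975, names = FALSE))
  # undefined draws are reported, not silently dropped
  bad <- data.frame(beta2 = c(rep(1, 150), -1, rep(1, 49)))
  suppressWarnings(
    expect_error(propagate(bad, function(d) log(d$beta2)), "151"))
  expect_error(propagate(data.frame(x = 1:10), identity), "100")
})

test_that("plug-in equals draw-wise only for linear transforms", {
  set.seed(6)
  dr <- data.frame(a = rnorm(5000, 2, 0.5), b = rnorm(5000, -1, 0.2))
  lin <- propagate(dr, function(d) 3 * d$a + d$b)
  expect_equal(lin$mean, 3 * mean(dr$a) + mean(dr$b), tolerance = 1e-10)
  nl <- propagate(dr, function(d) exp(d$a))
  expect_gt(nl$mean, exp(mean(dr$a)))  # Jensen gap
})

test_that("carbon impacts scale the capacity drop over the estate", {
  ci <- carbon_impact(0.24, 450, 1e6)
  expect_equal(ci$carbon_loss_t, 1.08e8)
  expect_equal(ci$carbon_loss_mt, 108)
  expect_equal(ci$equivalent_area_ha, 240000)
  expect_equal(ci$car_equivalent_people, 986301.4, tolerance = 1e-4)
  # invariants
  expect_equal(ci$carbon_loss_t,
               ci$drop_fraction * ci$carbon_per_ha * ci$area_ha)
  expect_equal(ci$equivalent_area_ha, ci$drop_fraction * ci$area_ha)
  expect_error(carbon_impact(0), "drop_fraction")
  expect_error(carbon_impact(1.2), "drop_fraction")
})

test_that("warming projections propagate fitted uncertainty", {
  ds <- small_dataset(seed = 41, n_plots = 15, n_control = 8)
  fit <- fit_mortality(ds$periods, "composite", n_draws = 400)
  pr <- project_warming(fit, 3)
  expect_lt(pr$multiplier$lower, pr$multiplier$mean)
  expect_lt(pr$multiplier$mean, pr$multiplier$upper)
  expect_equal(pr$percent_change, 100 * (pr$multiplier$mean - 1))
  stl <- stl_summary(fit)
  expect_lt(stl$slope$mean, 0)
  expect_lt(stl$intercept$lower, stl$intercept$upper)
  # scalar form
  pr0 <- project_warming(-0.09, 3)
  expect_equal(pr0$multiplier, 0.7634, tolerance = 1e-4)
})

test_that("trajectories respond to transient vs permanent warming", {
  base <- simulate_trajectory(scenario = "baseline", horizon = 150)
  same <- simulate_trajectory(scenario = "permanent", delta_t = 0,
                              horizon = 150)
  expect_equal(base$N, same$N)  # zero shift reproduces the baseline
  perm <- simulate_trajectory(scenario = "permanent", delta_t = 3,
                              horizon = 150)
  truth <- truth_params()
  mult <- capacity_multiplier(
    intercept_effect(truth$beta5, truth$beta2), 3)
  d_match <- min(max(base$D), max(perm$D)) * 0.98
  ratio <- exp(trajectory_logN_at(perm, d_match) -
                 trajectory_logN_at(base, d_match))
  expect_lt(abs(ratio - mult) / mult, 0.05)
  # transient dip recovers the baseline size-density trajectory
  trans <- simulate_trajectory(scenario = "transient", delta_t = 3,
                               window = c(20, 30), horizon = 150)
  during <- trans$time > 22 & trans$time < 32
  expect_true(any(log(trans$N[during]) <
                    log(base$N[match(trans$time[during], base$time)]) - 0.02))
  d_end <- min(max(base$D), max(trans$D)) * 0.98
  expect_lt(abs(trajectory_logN_at(trans, d_end) -
                  trajectory_logN_at(base, d_end)), 0.02)
  # stochastic mode is seed-reproducible
  s1 <- simulate_trajectory(mode = "stochastic", seed = 3, horizon = 60)
  s2 <- simulate_trajectory(mode = "stochastic", seed = 3, horizon = 60)
  expect_identical(s1, s2)
})
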