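test_that("generation is deterministic in the master seed", {
  a <- small_dataset(seed = 5)
  b <- small_dataset(seed = 5)
  expect_identical(a$periods, b$periods)
  expect_identical(a$climate, b$climate)
  c2 <- small_dataset(seed = 6)
  expect_false(identical(a$periods, c2$periods))
})

test_that("plot substreams are stable when the network grows", {
  a <- gen_dataset(small_config(n_plots = 6, n_control = 3), seed = 2)
  b <- gen_dataset(small_config(n_plots = 10, n_control = 3), seed = 2)
  expect_identical(a$periods[a$periods$plot_id == "P002", ],
                   b$periods[b$periods$plot_id == "P002", ])
})

test_that("climate series carry the warming trend and MAT-VPD coupling", {
  cfg <- generator_config()
  cl <- gen_climate(cfg, seed = 11)
  # flat series when trend and anomalies are off
  flat <- gen_climate(generator_config(warming = 0, anomaly_sd = 0),
                      seed = 11)
  one <- flat[flat$plot_id == "P001", ]
  expect_equal(diff(range(one$mat)), 0)
  # decade-mean contrast ~ linear-trend expectation within MC error
  first <- cl$mat[cl$year <= 1956]
  last <- cl$mat[cl$year >= 1991]
  expected <- cfg$warming * (mean(1991:2000) - mean(1947:1956)) /
    diff(cfg$years)
  se <- cfg$anomaly_sd * sqrt(1 / length(first) + 1 / length(last))
  expect_lt(abs((mean(last) - mean(first)) - expected), 3 * se)
  # VPD tracks MAT strongly (defined from 1980 on)
  post <- cl[!is.na(cl$vpd), ]
  expect_true(all(post$year >= 1980))
  expect_gte(cor(post$mat, post$vpd), 0.9)
  expect_true(all(cl$precip > 0))
})

test_that("default network emulates the study structure", {
  ds <- gen_dataset(seed = 1)
  expect_equal(length(unique(ds$periods$plot_id)), 112L)
  rem <- tapply(ds$periods$removed_N, ds$periods$plot_id,
                function(x) all(x == 0))
  expect_equal(sum(rem), 40L)  # unthinned controls
  expect_equal(control_plots(ds$periods, ds$plots),
               sort(names(rem)[rem]))
  expect_true(all(ds$periods$area_m2 >= 400 & ds$periods$area_m2 <= 8000))
  expect_true(all(ds$periods$interval >= 2 - 1e-9))
  # area distribution centered near the study mean of ~2600 m2
  areas <- unique(ds$periods[, c("plot_id", "area_m2")])$area_m2
  expect_gt(mean(areas), 2000); expect_lt(mean(areas), 3300)
  # filtering loses only a small fraction of periods at defaults
  flt <- apply_filters(ds$periods, ds$plots)
  expect_lt(mean(!flt$retained), 0.10)
})

test_that("mortality is climate-symmetric when effects are off", {
  truth0 <- truth_params(beta3 = 0, beta4 = 0, beta5 = 0, sigma_beta0 = 0)
  # identical stand state at different climates -> identical expected count
  lp1 <- linear_predictor(truth0, 30, 800, 1.2, 200, mat_period_c = -2)
  lp2 <- linear_predictor(truth0, 30, 800, 1.2, 200, mat_period_c = 2)
  expect_equal(lp1, lp2)
})

test_that("trajectories stay below the truth self-thinning line", {
  truth <- truth_params(sigma_beta0 = 0)  # isolate the population line
  ds <- gen_dataset(small_config(n_plots = 12, n_control = 12),
                    truth = truth, seed = 21)
  line <- stl_from_params(truth$beta0, truth$beta1, truth$beta2)
  eff <- intercept_effect(truth$beta5, truth$beta2)
  per <- ds$periods
  burn <- unlist(tapply(seq_len(nrow(per)), per$plot_id,
                        function(i) i[-(1:2)]))
  per <- per[burn, ]
  bound <- line$intercept + eff * (per$mat_longterm - 11) +
    line$slope * log(per$D_start)
  expect_true(all(log(per$N_start) <= bound + 0.20))
})

test_that("refitting with plot effects off recovers betas and tiny RE", {
  truth <- truth_params(sigma_beta0 = 0)
  ds <- gen_dataset(small_config(n_plots = 30, n_control = 30),
                    truth = truth, seed = 31)
  fit <- fit_mortality(ds$periods, "composite", mat_center = 11,
                       n_draws = 200)
  expect_lt(fit$sigma_beta0, 0.15)
  expect_lt(abs(fit$beta1 - truth$beta1), 0.5)
  expect_lt(abs(fit$beta2 - truth$beta2), 0.35)
})

test_that("tree-level expansion round-trips through the inventory path", {
  cfg <- generator_config(n_plots = 4, n_control = 2,
                          area_range = c(400, 1200), init_d = c(15, 25))
  ds <- gen_dataset(cfg, seed = 11, tree_level = TRUE)
  per <- build_periods(ds$inventory, ds$plots)
  m <- merge(ds$periods, per, by = c("plot_id", "start"),
             suffixes = c(".gen", ".re"))
  expect_equal(nrow(m), nrow(ds$periods))
  expect_equal(m$delta_N.re, m$delta_N.gen)
  expect_equal(m$removed_N.re, m$removed_N.gen)
  expect_equal(m$N_raw_start.re, m$N_raw_start.gen)
  expect_equal(m$delta_D.re, m$delta_D.gen, tolerance = 1e-9)
  expect_equal(m$D_start.re, m$D_start.gen, tolerance = 1e-9)
})

test_that("datasets write and re-read through the CSV interfaces", {
  dir <- tempfile("ds")
  cfg <- generator_config(n_plots = 3, n_control = 2,
                          area_range = c(400, 1000))
  ds <- gen_dataset(cfg, seed = 13, tree_level = TRUE)
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir,
    c("periods.csv", "plots.csv", "climate.csv", "inventory.csv")))))
  inv <- read_inventory_csv(file.path(dir, "inventory.csv"))
  expect_equal(nrow(inv), nrow(ds$inventory))
  per2 <- build_periods(inv, ds$plots)
  expect_equal(nrow(per2), nrow(ds$periods))
})
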