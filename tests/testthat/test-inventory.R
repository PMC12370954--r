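test_that("quadratic mean diameter matches hand arithmetic and bounds", {
  expect_equal(quadratic_mean_diameter(c(10, 10, 10)), 10)
  expect_equal(quadratic_mean_diameter(c(30, 40)), 35.355339, tolerance = 1e-6)
  expect_equal(quadratic_mean_diameter(25), 25)
  expect_error(quadratic_mean_diameter(numeric(0)), "empty")
  expect_error(quadratic_mean_diameter(c(10, -1)), "positive")
  # QMD >= arithmetic mean (Cauchy-Schwarz), equality iff all equal
  set.seed(1)
  for (i in 1:50) {
    x <- runif(sample(2:30, 1), 1, 100)
    expect_gte(quadratic_mean_diameter(x), mean(x))
  }
})

test_that("census summaries give density, QMD and basal-area share", {
  trees <- data.frame(tree_id = paste0("t", 1:26), dbh = rep(20, 26),
                      status = "alive", species = "E_regnans")
  s <- summarize_census(trees, area = 2600, target_species = "E_regnans")
  expect_equal(s$N, 100)           # 26 alive on 2600 m2
  expect_equal(s$N_raw, 26L)
  expect_equal(s$basal_area_share_target, 1.0)
  # two alive trees dbh 10 and 20, only the 20 is target: share 400/500
  trees2 <- data.frame(tree_id = c("a", "b"), dbh = c(10, 20),
                       status = "alive", species = c("other", "target"))
  s2 <- summarize_census(trees2, 1000, "target")
  expect_equal(s2$basal_area_share_target, 0.8)
  # zero alive trees: flagged, not NaN-propagated
  dead <- data.frame(tree_id = "x", dbh = 30, status = "dead",
                     species = "E_regnans")
  s3 <- summarize_census(dead, 1000, "E_regnans")
  expect_false(s3$qmd_defined)
  expect_equal(s3$N, 0)
  expect_error(summarize_census(trees, area = 0), "positive")
})

test_that("periods carry interval, mortality and removal bookkeeping", {
  per <- build_periods(toy_inventory(), toy_meta())
  expect_equal(nrow(per), 1L)
  expect_equal(per$interval, 2.5)
  expect_equal(per$delta_N, 1L)      # one death
  expect_equal(per$removed_N, 1L)    # removal never counted as mortality
  expect_equal(per$N_raw_start, 5L)
  expect_equal(per$D_start, quadratic_mean_diameter(c(10, 12, 14, 16, 18)))
  # delta_D from live trees at each census
  expect_equal(per$delta_D,
               quadratic_mean_diameter(c(12.8, 17.1, 19.2)) - per$D_start)
  expect_equal(per$D_dead, 10.5)     # QMD of the single dead tree
})

test_that("thinning-only periods record zero mortality", {
  inv <- toy_inventory()
  inv$status[6:10] <- c("removed", "removed", "alive", "alive", "alive")
  per <- build_periods(inv, toy_meta())
  expect_equal(per$delta_N, 0L)
  expect_equal(per$removed_N, 2L)
})

test_that("duplicate dates error; unmatched ids warn and are excluded", {
  inv <- toy_inventory()
  dup <- rbind(inv, inv[1, ])
  expect_error(build_periods(dup, toy_meta()), "duplicate")
  ingrowth <- rbind(inv, data.frame(plot_id = "A", census_date = 1972.5,
                                    tree_id = "t99", dbh = 5,
                                    status = "alive", species = "E_regnans"))
  expect_warning(per <- build_periods(ingrowth, toy_meta()), "no match")
  expect_equal(attr(per, "unmatched"), "A:t99")
  expect_equal(per$N_raw_start, 5L)
})

test_that("a single census yields zero periods", {
  inv <- toy_inventory()
  inv <- inv[inv$census_date == 1970.0, ]
  expect_equal(nrow(build_periods(inv, toy_meta())), 0L)
})

test_that("selection filters match the plot/period criteria", {
  base <- data.frame(plot_id = paste0("P", 1:6),
                     area_m2 = c(350, rep(2600, 5)),
                     interval = c(2.5, 2.5, 0.4, 2.5, 2.5, 2.5),
                     delta_D = c(1, 1, 1, 0.2, 1, 1),
                     ba_share_start = c(1, 1, 1, 1, 0.7, 1),
                     delta_N = 0, removed_N = 0)
  meta <- data.frame(plot_id = paste0("P", 1:6),
                     disturbed = c(rep(FALSE, 5), TRUE))
  out <- apply_filters(base, meta)
  expect_equal(sum(out$retained), 1L)
  expect_equal(out$exclusion_reason[1], "area")        # 350 m2 < 400
  expect_equal(out$exclusion_reason[3], "interval")
  expect_equal(out$exclusion_reason[4], "growth")      # 0.08 cm/yr < 0.1
  expect_equal(out$exclusion_reason[5], "purity")
  expect_equal(out$exclusion_reason[6], "disturbance")
  # 6 periods, 2 violating one rule each -> 4 retained
  toy <- base[c(2, 2, 2, 2, 1, 4), ]
  toy$plot_id <- paste0("Q", 1:6)
  out2 <- apply_filters(toy, NULL)
  expect_equal(sum(out2$retained), 4L)
})

test_that("filters are order-independent (conjunction of rules)", {
  set.seed(42)
  per <- data.frame(plot_id = paste0("P", 1:200),
                    area_m2 = runif(200, 300, 3000),
                    interval = runif(200, 0.2, 3),
                    delta_D = runif(200, 0, 1),
                    ba_share_start = runif(200, 0.6, 1))
  full <- apply_filters(per, NULL)
  keep <- rep(TRUE, 200)
  for (rule in sample(1:4)) {  # apply single rules in random order
    crit <- switch(rule,
      filter_criteria(min_area = 400, min_interval = 0, min_ba_share = 0,
                      min_annual_delta_D = 0),
      filter_criteria(min_area = 0, min_interval = 0.5, min_ba_share = 0,
                      min_annual_delta_D = 0),
      filter_criteria(min_area = 0, min_interval = 0, min_ba_share = 0.8,
                      min_annual_delta_D = 0),
      filter_criteria(min_area = 0, min_interval = 0, min_ba_share = 0,
                      min_annual_delta_D = 0.1))
    keep <- keep & apply_filters(per, NULL, crit)$retained
  }
  expect_equal(keep, full$retained)
})

test_that("generated periods conserve trees and reproduce N from N_raw", {
  ds <- small_dataset(seed = 7)
  per <- ds$periods
  # N * area/1e4 reproduces the integer live count exactly
  expect_equal(per$N_start * per$area_m2 / 1e4, as.numeric(per$N_raw_start),
               tolerance = 1e-9)
  # conservation within each plot: next start count = start - dead - removed
  for (pid in unique(per$plot_id)) {
    pp <- per[per$plot_id == pid, ]
    if (nrow(pp) < 2) next
    expect_equal(pp$N_raw_start[-1],
                 (pp$N_raw_start - pp$delta_N - pp$removed_N)[-nrow(pp)])
  }
})
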