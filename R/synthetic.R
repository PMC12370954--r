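#' Ground-truth parameters for the synthetic stand generator
#'
#' Defaults are the published posterior means from
#' [mountain_ash_params()] so that recovery tests target realistic
#' values. The growth submodel parameters are the generator's own: annual
#' QMD increment `g = g_max * exp(-D / D_scale) * (1 - growth_c * N / N_max(D))`
#' with lognormal noise, where `N_max(D)` is the plot's (climate-shifted)
#' self-thinning line — growth slows with size and as the stand approaches
#' the line.
#'
#' @param ... overrides for any field.
#' @return list of class `truth_params`: `alpha*`/`sigma*` for the static
#'   allometry, `beta*`/`theta` for the mortality models, `k_true` and
#'   `k_noise_sd` for dead-tree relative size, and `g_max` (cm/yr),
#'   `D_scale` (cm), `growth_c`, `growth_sd` for the growth submodel.
#' @export
truth_params <- function(...) {
  ref <- mountain_ash_params()
  p <- list(
    alpha0 = ref$static$alpha0, alpha1 = ref$static$alpha1,
    alpha2 = ref$static$alpha2, sigma_alpha0 = ref$static$sigma_alpha0,
    sigma = ref$static$sigma,
    beta0 = ref$eq_composite$beta0, beta1 = ref$eq_composite$beta1,
    beta2 = ref$eq_composite$beta2,
    beta3 = ref$eq_spacetime$beta3, beta4 = ref$eq_spacetime$beta4,
    beta5 = ref$eq_composite$beta5,
    sigma_beta0 = ref$eq_composite$sigma_beta0,
    theta = ref$eq_composite$theta,
    k_true = ref$k_factor, k_noise_sd = 0.1,
    g_max = 1.2, D_scale = 80, growth_c = 0.5, growth_sd = 0.15)
  over <- list(...)
  stopifnot(all(names(over) %in% names(p)))
  p[names(over)] <- over
  stopifnot(p$theta > 0, p$sigma > 0, p$sigma_alpha0 >= 0,
            p$sigma_beta0 >= 0, p$k_true > 0, p$k_true < 1)
  structure(p, class = "truth_params")
}

#' Configuration of the synthetic plot network
#'
#' Defaults emulate the study system: 112 plots of which 40 are unthinned
#' controls, areas 400-8000 m2 (mean ~2600 m2), censuses every 2-3 years
#' within 1947-2000, a spatial MAT gradient of 9.5-12.5 deg C, a 0.71 deg C
#' warming trend over the record with interannual anomalies, annual
#' rainfall 1000-1600 mm, and VPD strongly correlated with MAT.
#'
#' @param n_plots number of plots.
#' @param n_control number of unthinned control plots (the first
#'   `n_control` ids).
#' @param area_range plot-area bounds (m2); areas are drawn from a
#'   right-skewed Beta so the mean is ~2600 m2.
#' @param census_interval min/max years between censuses.
#' @param years record window (first/last calendar year).
#' @param mat_range spatial MAT gradient bounds (deg C).
#' @param warming total linear MAT trend over the window (deg C).
#' @param anomaly_sd interannual MAT anomaly SD (deg C).
#' @param precip_range plot mean annual rainfall bounds (mm).
#' @param precip_cv lognormal CV of annual rainfall around the plot mean.
#' @param vpd_base,vpd_slope,vpd_noise_sd VPD (kPa) as an affine function
#'   of MAT plus noise; defaults give a MAT-VPD correlation of ~0.96.
#'   VPD is only emitted from 1980 on.
#' @param init_d initial QMD bounds (cm).
#' @param init_frac initial density as a fraction of the plot's
#'   self-thinning-line density at the initial QMD.
#' @param start_years window from which a plot's first census is drawn.
#' @param thin_frac fraction of stems removed at the single mid-rotation
#'   thinning of non-control plots (a placeholder schedule; the real
#'   experiments' schedules are richer).
#' @param mortality_variant which mortality truth drives deaths:
#'   `"composite"` (period MAT, beta5) or `"spacetime"` (beta3/beta4).
#' @param min_trees stop censusing a plot below this live count.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_plots = 112, n_control = 40,
                             area_range = c(400, 8000),
                             census_interval = c(2, 3),
                             years = c(1947, 2000),
                             mat_range = c(9.5, 12.5),
                             warming = 0.71, anomaly_sd = 0.45,
                             precip_range = c(1000, 1600), precip_cv = 0.08,
                             vpd_base = 0.6, vpd_slope = 0.09,
                             vpd_noise_sd = 0.025,
                             init_d = c(10, 20), init_frac = c(0.55, 0.75),
                             start_years = c(1955, 1975),
                             thin_frac = 0.30,
                             mortality_variant = c("composite", "spacetime"),
                             min_trees = 5) {
  stopifnot(n_control <= n_plots, diff(area_range) > 0,
            diff(census_interval) >= 0, diff(years) > 0,
            diff(mat_range) > 0, diff(init_d) > 0, diff(init_frac) > 0)
  structure(list(n_plots = n_plots, n_control = n_control,
                 area_range = area_range, census_interval = census_interval,
                 years = years, mat_range = mat_range, warming = warming,
                 anomaly_sd = anomaly_sd, precip_range = precip_range,
                 precip_cv = precip_cv, vpd_base = vpd_base,
                 vpd_slope = vpd_slope, vpd_noise_sd = vpd_noise_sd,
                 init_d = init_d, init_frac = init_frac,
                 start_years = start_years, thin_frac = thin_frac,
                 mortality_variant = match.arg(mortality_variant),
                 min_trees = min_trees),
            class = "generator_config")
}

# Deterministic per-plot substream seed: stable under changes to n_plots.
plot_seed <- function(master_seed, plot_index, stream = 0L) {
  as.integer((as.numeric(master_seed) * 1000003 + plot_index * 7919 +
                stream * 524287) %% 2147483647)
}

#' Generate annual climate series for the plot network
#'
#' Per plot: a baseline MAT from the spatial gradient, an annual MAT equal
#' to baseline + linear warming trend (centered on the window, total =
#' `warming`) + iid anomaly; lognormal annual rainfall around a plot
#' baseline; and VPD as an affine function of MAT plus noise, emitted only
#' from 1980 on (mirroring the availability of VPD products).
#'
#' @param config a [generator_config()].
#' @param seed master seed.
#' @return data.frame `plot_id, year, mat, precip, vpd`.
#' @export
gen_climate <- function(config = generator_config(), seed = 1) {
  yrs <- seq.int(config$years[1], config$years[2])
  span <- diff(config$years)
  out <- vector("list", config$n_plots)
  for (j in seq_len(config$n_plots)) {
    set.seed(plot_seed(seed, j, stream = 1L))
    base_mat <- stats::runif(1, config$mat_range[1], config$mat_range[2])
    base_p <- stats::runif(1, config$precip_range[1], config$precip_range[2])
    trend <- config$warming * ((yrs - config$years[1]) / span - 0.5)
    mat <- base_mat + trend + stats::rnorm(length(yrs), 0, config$anomaly_sd)
    precip <- base_p * exp(stats::rnorm(length(yrs), 0, config$precip_cv))
    vpd <- config$vpd_base + config$vpd_slope * (mat - 9) +
      stats::rnorm(length(yrs), 0, config$vpd_noise_sd)
    vpd[yrs < 1980] <- NA_real_
    out[[j]] <- data.frame(plot_id = plot_label(j), year = yrs, mat = mat,
                           precip = precip, vpd = vpd,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

plot_label <- function(j) sprintf("P%03d", j)

#' Simulate one even-aged stand trajectory
#'
#' Iterates census to census: a QMD increment from the growth submodel,
#' then a negative-binomial mortality draw whose mean follows the
#' growth-mortality allocation model (log mu = plot intercept + beta1 log D
#' + beta2 log N + climate terms + log dD + log N_raw, covariates centered
#' at the dataset MAT center), truncated at the live count. Removals on
#' thinned plots are bookkept separately from deaths and never enter
#' `delta_N`. The dead-tree QMD is emitted per period as
#' `k_true * D_start * exp(N(0, k_noise_sd))`.
#'
#' @param plot_index integer plot index.
#' @param config a [generator_config()].
#' @param truth a [truth_params()].
#' @param climate annual climate rows for this plot (from [gen_climate()]).
#' @param seed master seed.
#' @param mat_center centering constant for MAT covariates.
#' @param thin logical: apply the single mid-rotation thinning.
#' @return data.frame of per-period records (one row per intercensus
#'   period) with start state, changes, dead QMD and period climate.
#' @export
gen_stand_trajectory <- function(plot_index, config, truth, climate,
                                 seed = 1, mat_center = 11, thin = FALSE) {
  set.seed(plot_seed(seed, plot_index, stream = 2L))
  area <- config$area_range[1] +
    diff(config$area_range) * stats::rbeta(1, 1, 2.45)
  b0j <- stats::rnorm(1, truth$beta0, truth$sigma_beta0)
  t0 <- stats::runif(1, config$start_years[1], config$start_years[2])
  D <- stats::runif(1, config$init_d[1], config$init_d[2])
  frac <- stats::runif(1, config$init_frac[1], config$init_frac[2])

  in_window <- climate$year >= 1960 & climate$year <= 2000
  mat_lt <- if (any(in_window)) mean(climate$mat[in_window]) else
    mean(climate$mat)
  eff <- intercept_effect(truth$beta5, truth$beta2)
  base_line <- stl_from_params(truth$beta0, truth$beta1, truth$beta2)
  int_j <- base_line$intercept + eff * (mat_lt - mat_center)
  n_max <- function(d) exp(int_j + base_line$slope * log(d))

  N <- frac * n_max(D)
  N_raw <- max(round(N * area / 1e4), config$min_trees)
  N <- N_raw / (area / 1e4)

  # decide thinning census up-front so the schedule is seed-stable
  thin_at <- if (thin) stats::runif(1, 0.3, 0.5) else NA  # fraction of record
  acc <- list(start = numeric(0), end = numeric(0), D_start = numeric(0),
              N_start = numeric(0), N_raw_start = integer(0),
              delta_N = integer(0), removed_N = integer(0),
              delta_D = numeric(0), D_dead = numeric(0),
              mat_period = numeric(0), mat_anomaly = numeric(0))
  t <- t0
  while (t < config$years[2] && N_raw >= config$min_trees) {
    dt <- stats::runif(1, config$census_interval[1], config$census_interval[2])
    if (t + dt > config$years[2] + 1) break  # record window closed
    t_end <- t + dt
    mat_ij <- period_mean(climate$year, climate$mat, t, t_end)
    anom <- mat_ij - mat_lt
    g <- truth$g_max * exp(-D / truth$D_scale) *
      (1 - truth$growth_c * min(N / n_max(D), 1.2))
    dD <- max(g, 0.05) * (t_end - t) * exp(stats::rnorm(1, 0, truth$growth_sd))

    clim_term <- if (config$mortality_variant == "composite") {
      truth$beta5 * (mat_ij - mat_center)
    } else {
      truth$beta3 * (mat_lt - mat_center) + truth$beta4 * anom
    }
    log_mu <- b0j + truth$beta1 * log(D) + truth$beta2 * log(N) +
      clim_term + log(dD) + log(N_raw)
    if (!is.finite(log_mu)) stop("gen_stand_trajectory: non-finite mean")
    dN <- min(stats::rnbinom(1, mu = exp(log_mu), size = truth$theta), N_raw)

    removed <- 0L
    if (thin && !is.na(thin_at) &&
        (t - t0) / (config$years[2] - t0) >= thin_at) {
      removed <- round(config$thin_frac * (N_raw - dN))
      thin_at <- NA  # single event
    }
    d_dead <- if (dN >= 1) {
      truth$k_true * D * exp(stats::rnorm(1, 0, truth$k_noise_sd))
    } else NA_real_

    acc$start <- c(acc$start, t); acc$end <- c(acc$end, t_end)
    acc$D_start <- c(acc$D_start, D); acc$N_start <- c(acc$N_start, N)
    acc$N_raw_start <- c(acc$N_raw_start, N_raw)
    acc$delta_N <- c(acc$delta_N, dN)
    acc$removed_N <- c(acc$removed_N, removed)
    acc$delta_D <- c(acc$delta_D, dD); acc$D_dead <- c(acc$D_dead, d_dead)
    acc$mat_period <- c(acc$mat_period, mat_ij)
    acc$mat_anomaly <- c(acc$mat_anomaly, anom)

    N_raw <- N_raw - dN - removed
    if (N_raw < 1) break
    N <- N_raw / (area / 1e4)
    D <- D + dD
    t <- t_end
  }
  if (length(acc$start) == 0L) return(NULL)
  data.frame(plot_id = plot_label(plot_index), start = acc$start,
             end = acc$end, interval = acc$end - acc$start, area_m2 = area,
             D_start = acc$D_start, N_start = acc$N_start,
             N_raw_start = acc$N_raw_start, delta_N = acc$delta_N,
             removed_N = acc$removed_N, delta_D = acc$delta_D,
             D_dead = acc$D_dead, ba_share_start = 1,
             mat_period = acc$mat_period, mat_longterm = mat_lt,
             mat_anomaly = acc$mat_anomaly, stringsAsFactors = FALSE)
}

#' Generate a full synthetic dataset
#'
#' Produces the period table driving every downstream model, the annual
#' climate series, plot metadata, and (optionally) a per-tree long-format
#' inventory consistent with the period summaries for exercising the
#' inventory-processing interface on small configurations.
#'
#' @param config a [generator_config()].
#' @param truth a [truth_params()].
#' @param seed master seed; identical seeds give identical datasets.
#' @param tree_level also build the per-tree inventory (memory-heavy for
#'   the full default network; intended for small configs).
#' @return list with `periods`, `climate`, `plots` (metadata:
#'   `plot_id, area_m2, disturbed, thinned`), `truth`, `config`, `seed`,
#'   and `inventory` when `tree_level = TRUE`. Periods also carry
#'   `precip`, `ahmi`, `vpd`, `year_mid` covariates.
#' @export
gen_dataset <- function(config = generator_config(), truth = truth_params(),
                        seed = 1, tree_level = FALSE) {
  climate <- gen_climate(config, seed)
  mat_center <- mountain_ash_params()$climate$mat_center
  per <- vector("list", config$n_plots)
  for (j in seq_len(config$n_plots)) {
    cl <- climate[climate$plot_id == plot_label(j), ]
    per[[j]] <- gen_stand_trajectory(j, config, truth, cl, seed = seed,
                                     mat_center = mat_center,
                                     thin = j > config$n_control)
  }
  periods <- do.call(rbind, per[!vapply(per, is.null, logical(1))])
  rownames(periods) <- NULL
  # attach the remaining covariates from the climate series
  cl_split <- split(climate, climate$plot_id)
  periods$precip <- NA_real_
  periods$vpd <- NA_real_
  for (i in seq_len(nrow(periods))) {
    cl <- cl_split[[periods$plot_id[i]]]
    periods$precip[i] <- period_mean(cl$year, cl$precip,
                                     periods$start[i], periods$end[i])
    ok <- !is.na(cl$vpd)
    periods$vpd[i] <- if (any(ok) && floor(periods$start[i]) >= min(cl$year[ok]))
      period_mean(cl$year[ok], cl$vpd[ok], periods$start[i], periods$end[i])
    else NA_real_
  }
  periods$ahmi <- ahmi(periods$mat_period, periods$precip)
  periods$year_mid <- (periods$start + periods$end) / 2
  plots <- data.frame(
    plot_id = plot_label(seq_len(config$n_plots)),
    area_m2 = periods$area_m2[match(plot_label(seq_len(config$n_plots)),
                                    periods$plot_id)],
    disturbed = FALSE,
    thinned = seq_len(config$n_plots) > config$n_control,
    stringsAsFactors = FALSE)
  ds <- list(periods = periods, climate = climate, plots = plots,
             truth = truth, config = config, seed = seed)
  if (tree_level) ds$inventory <- expand_tree_inventory(ds, seed)
  ds
}

# Expand period summaries into a consistent per-tree long-format inventory:
# initial DBHs are lognormal rescaled to the exact starting QMD; each
# period the delta_N smallest live trees die and removed_N random live
# trees are removed; survivors are rescaled so their QMD matches the next
# census' QMD exactly.
expand_tree_inventory <- function(ds, seed = 1) {
  inv <- list()
  for (pid in unique(ds$periods$plot_id)) {
    pp <- ds$periods[ds$periods$plot_id == pid, , drop = FALSE]
    pp <- pp[order(pp$start), , drop = FALSE]
    set.seed(plot_seed(seed, match(pid, ds$plots$plot_id), stream = 3L))
    n0 <- pp$N_raw_start[1]
    dbh <- stats::rlnorm(n0, log(pp$D_start[1]), 0.25)
    dbh <- dbh * pp$D_start[1] / quadratic_mean_diameter(dbh)
    ids <- paste0(pid, "-T", seq_len(n0))
    status <- rep("alive", n0)
    add_census <- function(date) {
      data.frame(plot_id = pid, census_date = date, tree_id = ids,
                 dbh = dbh, status = status, species = "E_regnans",
                 stringsAsFactors = FALSE)[status != "gone", , drop = FALSE]
    }
    inv[[length(inv) + 1L]] <- add_census(pp$start[1])
    for (k in seq_len(nrow(pp))) {
      alive <- which(status == "alive")
      dn <- min(pp$delta_N[k], length(alive))
      dying <- alive[order(dbh[alive])][seq_len(dn)]
      status[dying] <- "dead"
      alive <- setdiff(alive, dying)
      rm_n <- min(pp$removed_N[k], length(alive))
      removed <- if (rm_n > 0) sample(alive, rm_n) else integer(0)
      status[removed] <- "removed"
      alive <- setdiff(alive, removed)
      d_next <- pp$D_start[k] + pp$delta_D[k]
      if (length(alive) > 0) {
        dbh[alive] <- dbh[alive] * d_next / quadratic_mean_diameter(dbh[alive])
      }
      inv[[length(inv) + 1L]] <- add_census(pp$end[k])
      status[status %in% c("dead", "removed")] <- "gone"
    }
  }
  out <- do.call(rbind, inv)
  rownames(out) <- NULL
  out
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits `periods.csv`, `plots.csv`, `climate.csv`, a `truth.json` echoing
#' all truth parameters, the config and the seed, and `inventory.csv` when
#' the dataset was built tree-level.
#'
#' @param ds result of [gen_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(ds$periods, file.path(dir, "periods.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$plots, file.path(dir, "plots.csv"), row.names = FALSE)
  utils::write.csv(ds$climate, file.path(dir, "climate.csv"),
                   row.names = FALSE)
  if (!is.null(ds$inventory)) {
    inv <- ds$inventory
    names(inv)[names(inv) == "dbh"] <- "dbh_cm"
    utils::write.csv(inv, file.path(dir, "inventory.csv"), row.names = FALSE)
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(truth = unclass(ds$truth), config = unclass(ds$config),
           seed = ds$seed),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
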