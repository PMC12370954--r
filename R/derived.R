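#' Self-thinning line parameters from mortality-model coefficients
#'
#' In the growth-mortality allocation model, the self-thinning line
#' log N = intercept + slope * log D is the stationary trajectory of the
#' mortality process, with
#' `intercept = beta0/(-beta2) + (log(beta2) - log(beta1 + 1))/(-beta2)`
#' and `slope = (1 + beta1)/(-beta2)`. The log terms are small but are
#' included exactly. Vectorized over parameter draws.
#'
#' @param beta0,beta1,beta2 mortality-model coefficients
#'   (`beta2 > 0`, `beta1 + 1 > 0`).
#' @return list with `intercept` (log trees/ha at log D = 0) and `slope`.
#' @examples
#' stl_from_params(-29.61, 2.95, 2.40) # intercept 12.55, slope -1.65
#' @export
stl_from_params <- function(beta0, beta1, beta2) {
  if (any(beta2 <= 0)) stop("stl_from_params: beta2 must be > 0")
  if (any(beta1 + 1 <= 0)) stop("stl_from_params: beta1 + 1 must be > 0")
  list(intercept = beta0 / (-beta2) + (log(beta2) - log(beta1 + 1)) / (-beta2),
       slope = (1 + beta1) / (-beta2))
}

#' Per-degree climate effect on the self-thinning intercept
#'
#' A climate coefficient `beta_k` in the mortality model maps to an
#' additive shift `beta_k / (-beta2)` of the self-thinning intercept per
#' degree C.
#'
#' @param beta_k climate coefficient (e.g. on period MAT).
#' @param beta2 coefficient on log N, nonzero.
#' @return additive intercept shift per deg C (log scale).
#' @examples
#' intercept_effect(0.22, 2.40) # -0.0917
#' @export
intercept_effect <- function(beta_k, beta2) {
  if (any(beta2 == 0)) stop("intercept_effect: beta2 must be nonzero")
  beta_k / (-beta2)
}

#' Multiplicative change in carrying capacity under warming
#'
#' `exp(effect * delta_t)`: the factor by which the maximum density at a
#' given QMD is multiplied when temperature rises by `delta_t` deg C.
#'
#' @param effect per-degree additive intercept shift (log scale).
#' @param delta_t temperature change (deg C).
#' @return multiplier (> 0); e.g. effect -0.09 with +3 deg C gives 0.76.
#' @export
capacity_multiplier <- function(effect, delta_t) {
  exp(effect * delta_t)
}

#' Propagate parameter uncertainty through a derived quantity
#'
#' Applies a transform draw-wise to joint parameter draws and summarizes
#' the resulting distribution by its mean and central 95% interval. The
#' transform is never applied to summary means to build intervals.
#'
#' @param draws data.frame or matrix of joint draws (rows = draws).
#' @param transform function taking the draws table and returning one
#'   numeric value per row (vectorized over rows).
#' @param probs interval probabilities.
#' @return list `mean`, `lower`, `upper`, `values` (the per-draw values).
#' @export
propagate <- function(draws, transform, probs = c(0.025, 0.975)) {
  draws <- as.data.frame(draws)
  if (nrow(draws) < 100L) {
    stop("propagate: need at least 100 joint draws, got ", nrow(draws))
  }
  v <- transform(draws)
  if (length(v) != nrow(draws)) {
    stop("propagate: transform must return one value per draw")
  }
  bad <- which(!is.finite(v))
  if (length(bad) > 0L) {
    stop("propagate: transform undefined on draw(s) ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "")
  }
  q <- stats::quantile(v, probs, names = FALSE)
  list(mean = mean(v), lower = q[1], upper = q[2], values = v)
}

#' Self-thinning line summary from a fitted mortality model
#'
#' Propagates the joint coefficient draws of a [fit_mortality()] result
#' through the closed forms for the intercept, slope and per-degree
#' climate effect(s) of the self-thinning line.
#'
#' @param fit a `mortality_fit`.
#' @return list of class `self_thinning_line` with `intercept`, `slope`
#'   and one entry per climate effect, each a `mean/lower/upper` summary.
#' @export
stl_summary <- function(fit) {
  stopifnot(inherits(fit, "mortality_fit"))
  d <- as.data.frame(fit$draws)
  out <- list(
    intercept = propagate(d, function(x)
      stl_from_params(x$beta0, x$beta1, x$beta2)$intercept),
    slope = propagate(d, function(x)
      stl_from_params(x$beta0, x$beta1, x$beta2)$slope))
  for (nm in intersect(c("beta3", "beta4", "beta5"), names(d))) {
    out[[paste0("effect_", nm)]] <-
      propagate(d, function(x) intercept_effect(x[[nm]], x$beta2))
  }
  structure(out, class = "self_thinning_line")
}

#' Warming projection for carrying capacity
#'
#' Computes the capacity multiplier and percent change for a temperature
#' shift, either from a scalar per-degree effect or draw-wise from a
#' fitted mortality model (climate-effect uncertainty propagated).
#'
#' @param x a scalar per-degree effect or a `mortality_fit`.
#' @param delta_t temperature change (deg C).
#' @param effect_param which coefficient to use for a fit
#'   (default the fit's climate coefficient: `beta5` or `beta4`).
#' @return list with `delta_t`, `multiplier` (summary or scalar) and
#'   `percent_change` (= 100 * (multiplier - 1), negative for a decline).
#' @export
project_warming <- function(x, delta_t, effect_param = NULL) {
  if (inherits(x, "mortality_fit")) {
    d <- as.data.frame(x$draws)
    if (is.null(effect_param)) {
      effect_param <- if ("beta5" %in% names(d)) "beta5" else "beta4"
    }
    mult <- propagate(d, function(z)
      capacity_multiplier(intercept_effect(z[[effect_param]], z$beta2),
                          delta_t))
    list(delta_t = delta_t, multiplier = mult[c("mean", "lower", "upper")],
         percent_change = 100 * (mult$mean - 1))
  } else {
    m <- capacity_multiplier(x, delta_t)
    list(delta_t = delta_t, multiplier = m, percent_change = 100 * (m - 1))
  }
}

#' Carbon-stock impact of a carrying-capacity drop
#'
#' Scales a fractional capacity decline over a forest estate:
#' `carbon_loss = drop_fraction * carbon_per_ha * area`, with the
#' equivalent mature-forest area `carbon_loss / carbon_per_ha` and an
#' optional car-commute equivalence (people driving `km_per_yr` for
#' `years` at `car_g_per_km` grams of carbon per km).
#'
#' @param drop_fraction fractional capacity decline in (0, 1).
#' @param carbon_per_ha carbon density (t C/ha), default the
#'   typical-stand 450 t C/ha.
#' @param area_ha estate area (ha), default one million ha of tall-open
#'   wet forest.
#' @param car_g_per_km,km_per_yr,years car-equivalence constants.
#' @return list with `drop_fraction`, `carbon_per_ha`, `area_ha`,
#'   `carbon_loss_t`, `carbon_loss_mt` (million tonnes),
#'   `equivalent_area_ha`, `car_equivalent_people`.
#' @export
carbon_impact <- function(drop_fraction, carbon_per_ha = 450, area_ha = 1e6,
                          car_g_per_km = 146, km_per_yr = 1e4, years = 75) {
  stopifnot(drop_fraction > 0, drop_fraction < 1, carbon_per_ha > 0,
            area_ha > 0)
  loss <- drop_fraction * carbon_per_ha * area_ha
  per_person_t <- car_g_per_km * km_per_yr * years / 1e6
  list(drop_fraction = drop_fraction, carbon_per_ha = carbon_per_ha,
       area_ha = area_ha, carbon_loss_t = loss, carbon_loss_mt = loss / 1e6,
       equivalent_area_ha = loss / carbon_per_ha,
       car_equivalent_people = loss / per_person_t)
}

#' Simulate a self-thinning trajectory under a warming scenario
#'
#' Iterates growth then mortality on a single stand: the QMD increment
#' comes from the growth submodel (or a user-supplied increment
#' function), and mortality follows the growth-mortality allocation
#' model, either as its expected value (`mode = "deterministic"`) or as
#' negative-binomial draws (`mode = "stochastic"`). Scenarios shift the
#' period MAT (composite-model mapping): `transient` adds `delta_t`
#' only inside `window` (a heatwave), `permanent` adds it from `onset`
#' on (climate warming). A permanent shift moves the stand onto a
#' self-thinning line lowered by `capacity_multiplier(effect, delta_t)`;
#' a transient one causes a dip followed by recovery toward the baseline
#' trajectory.
#'
#' @param truth a [truth_params()] (or a list with the same beta/growth
#'   fields, e.g. posterior means from a fit).
#' @param scenario `"baseline"`, `"transient"` or `"permanent"`.
#' @param delta_t temperature shift (deg C).
#' @param window `c(from, to)` years-from-start for the transient shift.
#' @param onset years-from-start at which the permanent shift begins.
#' @param init_d,init_frac initial QMD (cm) and density as a fraction of
#'   the baseline line.
#' @param area_m2 stand area.
#' @param horizon simulated span (years).
#' @param dt census interval (years).
#' @param mode `"deterministic"` (expected mortality) or `"stochastic"`.
#' @param growth_fun optional `function(D, N, n_max)` returning the annual
#'   QMD increment (cm/yr); default the growth submodel without noise.
#' @param seed used in stochastic mode.
#' @return data.frame `time, D, N, N_raw, mat_shift, collapsed`; the
#'   `collapsed` flag marks truncation below 2 live trees.
#' @export
simulate_trajectory <- function(truth = truth_params(),
                                scenario = c("baseline", "transient",
                                             "permanent"),
                                delta_t = 3, window = c(20, 30), onset = 20,
                                init_d = 15, init_frac = 0.65,
                                area_m2 = 2600, horizon = 120, dt = 2.5,
                                mode = c("deterministic", "stochastic"),
                                growth_fun = NULL, seed = 1) {
  scenario <- match.arg(scenario)
  mode <- match.arg(mode)
  if (mode == "stochastic") set.seed(seed)
  line <- stl_from_params(truth$beta0, truth$beta1, truth$beta2)
  eff <- intercept_effect(truth$beta5, truth$beta2)
  n_max <- function(d) exp(line$intercept + line$slope * log(d))
  if (is.null(growth_fun)) {
    growth_fun <- function(D, N, nm) {
      truth$g_max * exp(-D / truth$D_scale) *
        (1 - truth$growth_c * min(N / nm, 1.2))
    }
  }
  D <- init_d
  N <- init_frac * n_max(D)
  N_raw <- max(round(N * area_m2 / 1e4), 2)
  N <- N_raw / (area_m2 / 1e4)
  times <- seq(0, horizon, by = dt)
  out <- data.frame(time = times, D = NA_real_, N = NA_real_,
                    N_raw = NA_real_, mat_shift = NA_real_,
                    collapsed = FALSE)
  for (i in seq_along(times)) {
    shift <- switch(scenario,
      baseline = 0,
      transient = if (times[i] >= window[1] && times[i] < window[2])
        delta_t else 0,
      permanent = if (times[i] >= onset) delta_t else 0)
    out$D[i] <- D; out$N[i] <- N; out$N_raw[i] <- N_raw
    out$mat_shift[i] <- shift
    if (i == length(times)) break
    step <- times[i + 1] - times[i]
    dD <- max(growth_fun(D, N, n_max(D)), 0.02) * step
    mu <- exp(truth$beta0 + truth$beta1 * log(D) + truth$beta2 * log(N) +
                truth$beta5 * shift + log(dD) + log(N_raw))
    dN <- if (mode == "deterministic") mu else
      stats::rnbinom(1, mu = mu, size = truth$theta)
    N_raw <- max(N_raw - min(dN, N_raw), 0)
    if (N_raw < 2) {
      out$collapsed[(i + 1):length(times)] <- TRUE
      out <- out[seq_len(i), , drop = FALSE]
      break
    }
    N <- N_raw / (area_m2 / 1e4)
    D <- D + dD
  }
  out
}

#' Interpolate a trajectory's log density at given QMDs
#'
#' Linear interpolation of log N against log D, used to compare two
#' trajectories at matched mean tree size.
#'
#' @param traj result of [simulate_trajectory()].
#' @param d QMD values (cm) at which to evaluate.
#' @return log N at `d` (NA outside the trajectory's D range).
#' @export
trajectory_logN_at <- function(traj, d) {
  stats::approx(log(traj$D), log(traj$N), xout = log(d))$y
}
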