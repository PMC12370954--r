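#' Negative-binomial log-pmf (mean-shape parameterization)
#'
#' The mortality likelihood: `y ~ NB(mu, theta)` with mean `mu` and
#' variance `mu + mu^2 / theta`,
#' `log P(y) = lgamma(y + theta) - lgamma(theta) - lgamma(y + 1)
#'  + theta * log(theta / (theta + mu)) + y * log(mu / (theta + mu))`.
#' As `theta -> Inf` this tends to the Poisson log-pmf.
#'
#' @param y non-negative integer count(s).
#' @param mu mean(s), > 0.
#' @param theta shape(s), > 0.
#' @return log-probability, vectorized.
#' @export
nb_logpmf <- function(y, mu, theta) {
  if (any(y < 0) || any(y != round(y))) {
    stop("nb_logpmf: y must be a non-negative integer")
  }
  if (any(mu <= 0) || any(theta <= 0)) {
    stop("nb_logpmf: mu and theta must be > 0")
  }
  lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
    theta * log(theta / (theta + mu)) + y * log(mu / (theta + mu))
}

#' Linear predictor of the growth-mortality allocation model
#'
#' `log mu = intercept + beta1 log D + beta2 log N + climate terms +
#'  log dD + log N_raw`. The growth (`log dD`) and count (`log N_raw`)
#' offsets enter with coefficient fixed at exactly 1: mortality is
#' proportional to the QMD increment and to the number of trees at risk,
#' so `mu / N_raw` is a per-tree (area-free) rate. Climate terms:
#' `"composite"` uses `beta5 * mat_period_c`; `"spacetime"` uses
#' `beta3 * mat_longterm_c + beta4 * mat_anomaly`.
#'
#' @param params list with `beta0, beta1, beta2` and `beta5` or
#'   `beta3`/`beta4`.
#' @param D QMD (cm), `N` density (trees/ha), `delta_D` QMD increment
#'   (cm, > 0), `N_raw` live count — all > 0.
#' @param N,delta_D,N_raw see above.
#' @param mat_longterm_c,mat_anomaly,mat_period_c centered climate
#'   covariates (deg C).
#' @param variant `"composite"` or `"spacetime"`.
#' @return log mu, vectorized.
#' @export
linear_predictor <- function(params, D, N, delta_D, N_raw,
                             mat_longterm_c = 0, mat_anomaly = 0,
                             mat_period_c = 0,
                             variant = c("composite", "spacetime")) {
  variant <- match.arg(variant)
  if (any(D <= 0) || any(N <= 0) || any(N_raw <= 0)) {
    stop("linear_predictor: D, N and N_raw must be > 0")
  }
  if (any(delta_D <= 0)) {
    stop("linear_predictor: delta_D must be > 0 (filter upstream)")
  }
  clim <- if (variant == "composite") {
    params$beta5 * mat_period_c
  } else {
    params$beta3 * mat_longterm_c + params$beta4 * mat_anomaly
  }
  params$beta0 + params$beta1 * log(D) + params$beta2 * log(N) + clim +
    log(delta_D) + log(N_raw)
}

#' Fit the negative-binomial mortality GLMM
#'
#' Fits the growth-mortality allocation model to intercensus periods:
#' dead-tree counts with a log link, `log D` and `log N` predictors,
#' fixed offsets `log delta_D` and `log N_raw`, plot-level random
#' intercepts, and MAT either decomposed into its long-term (spatial)
#' mean and (temporal) anomaly (`variant = "spacetime"`) or as the
#' composite period MAT (`variant = "composite"`). Estimation is by ML
#' (glmmTMB, NB2 family); joint draws for all reported parameters are
#' sampled from the asymptotic normal of the estimator (log scale for
#' theta and the random-effect SD), giving draw-equivalents for
#' posterior-style propagation of derived quantities.
#'
#' @param periods table with `plot_id, D_start, N_start, N_raw_start,
#'   delta_N, delta_D, mat_longterm, mat_anomaly, mat_period`.
#' @param variant `"composite"` (period MAT) or `"spacetime"`.
#' @param mat_center optional centering constant for MAT covariates
#'   (defaults to the fitting-dataset mean).
#' @param include_interaction add the long-term x anomaly interaction
#'   (spacetime variant only; off by default).
#' @param n_draws number of joint draws.
#' @param seed seed for the draws.
#' @return object of class `mortality_fit`: coefficients, `sigma_beta0`,
#'   `theta`, Wald 95% intervals, plot intercepts, a `draws` data.frame
#'   (betas + `theta` + `sigma_beta0`), centers and the glmmTMB fit.
#' @export
fit_mortality <- function(periods, variant = c("composite", "spacetime"),
                          mat_center = NULL, include_interaction = FALSE,
                          n_draws = 1000, seed = 1) {
  variant <- match.arg(variant)
  need <- c("plot_id", "D_start", "N_start", "N_raw_start", "delta_N",
            "delta_D", "mat_longterm", "mat_anomaly", "mat_period")
  stopifnot(all(need %in% names(periods)))
  if (length(unique(periods$plot_id)) < 2L) {
    stop("fit_mortality: need >= 2 plots")
  }
  if (all(periods$delta_N == 0)) {
    stop("fit_mortality: no mortality anywhere; theta is unidentifiable")
  }
  if (any(periods$delta_D <= 0)) {
    stop("fit_mortality: delta_D <= 0 present; apply filters upstream")
  }
  if (is.null(mat_center)) mat_center <- mean(periods$mat_period)
  df <- data.frame(
    dN = periods$delta_N,
    logD = log(periods$D_start), logN = log(periods$N_start),
    off = log(periods$delta_D) + log(periods$N_raw_start),
    mat_lt_c = periods$mat_longterm - mat_center,
    anom = periods$mat_anomaly,
    mat_c = periods$mat_period - mat_center,
    plot_id = factor(periods$plot_id))
  form <- if (variant == "composite") {
    dN ~ logD + logN + mat_c + (1 | plot_id) + offset(off)
  } else if (include_interaction) {
    dN ~ logD + logN + mat_lt_c * anom + (1 | plot_id) + offset(off)
  } else {
    dN ~ logD + logN + mat_lt_c + anom + (1 | plot_id) + offset(off)
  }
  fit <- glmmTMB::glmmTMB(form, family = glmmTMB::nbinom2, data = df)
  if (!is.null(fit$fit$convergence) && fit$fit$convergence != 0) {
    stop("fit_mortality: optimizer did not converge: ", fit$fit$message)
  }
  if (!fit$sdr$pdHess) {
    stop("fit_mortality: Hessian not positive definite (non-convergence)")
  }
  fe <- glmmTMB::fixef(fit)$cond
  beta_names <- if (variant == "composite") {
    c("beta0", "beta1", "beta2", "beta5")
  } else if (include_interaction) {
    c("beta0", "beta1", "beta2", "beta3", "beta4", "beta34")
  } else {
    c("beta0", "beta1", "beta2", "beta3", "beta4")
  }
  # joint asymptotic-normal draws over (betas, log theta, log sigma_b0)
  vc_full <- stats::vcov(fit, full = TRUE)
  keep <- seq_len(length(fe) + 2L)  # fixed effects + betadisp + theta
  mu_full <- c(fe, fit$fit$par[names(fit$fit$par) %in%
                                 c("betadisp", "betad")],
               fit$fit$par[names(fit$fit$par) == "theta"])
  set.seed(seed)
  dr <- MASS::mvrnorm(n_draws, mu = mu_full, Sigma = vc_full[keep, keep])
  draws <- as.data.frame(dr[, seq_along(fe), drop = FALSE])
  names(draws) <- beta_names
  draws$theta <- exp(dr[, length(fe) + 1L])
  draws$sigma_beta0 <- exp(dr[, length(fe) + 2L])
  ci <- stats::confint(fit, method = "wald")
  coefs <- as.list(fe)
  names(coefs) <- beta_names
  structure(c(coefs, list(
    sigma_beta0 = sqrt(glmmTMB::VarCorr(fit)$cond$plot_id[1]),
    theta = glmmTMB::sigma(fit),
    ci = ci[seq_along(fe), 1:2, drop = FALSE],
    plot_intercepts = glmmTMB::ranef(fit)$cond$plot_id[, 1],
    draws = draws, variant = variant, mat_center = mat_center,
    n_obs = nrow(df), n_plots = nlevels(df$plot_id), model = fit)),
    class = "mortality_fit")
}

#' @method print mortality_fit
#' @export
print.mortality_fit <- function(x, ...) {
  cat("NB mortality GLMM (", x$variant, " MAT, ", x$n_obs, " periods, ",
      x$n_plots, " plots)\n", sep = "")
  betas <- intersect(c("beta0", "beta1", "beta2", "beta3", "beta4",
                       "beta5"), names(x))
  for (b in betas) cat(sprintf("  %-6s %8.3f\n", b, x[[b]]))
  cat(sprintf("  theta  %8.3f   sigma_plot %6.3f\n", x$theta,
              x$sigma_beta0))
  invisible(x)
}

#' Predict expected mortality from a fitted model
#'
#' Evaluates mu draw-wise at the supplied stand state (plot effect at
#' its population mean, i.e. predictions for a new plot) and summarizes
#' the expected count and the per-tree rate `mu / N_raw`.
#'
#' @param fit a `mortality_fit`.
#' @param D,N,delta_D,N_raw stand state (see [linear_predictor()]).
#' @param mat_longterm,mat_anomaly,mat_period climate on the original
#'   scale (centered internally with the fit's constant).
#' @return list with `count` and `rate`, each `mean/lower/upper`.
#' @export
predict_mortality <- function(fit, D, N, delta_D, N_raw,
                              mat_longterm = NULL, mat_anomaly = 0,
                              mat_period = NULL) {
  stopifnot(inherits(fit, "mortality_fit"))
  mlt_c <- if (is.null(mat_longterm)) 0 else mat_longterm - fit$mat_center
  mp_c <- if (is.null(mat_period)) 0 else mat_period - fit$mat_center
  mu <- propagate(fit$draws, function(d)
    exp(linear_predictor(d, D, N, delta_D, N_raw,
                         mat_longterm_c = mlt_c, mat_anomaly = mat_anomaly,
                         mat_period_c = mp_c, variant = fit$variant)))
  rate <- lapply(mu[c("mean", "lower", "upper")], function(v) v / N_raw)
  list(count = mu[c("mean", "lower", "upper")], rate = rate)
}
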