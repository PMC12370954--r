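#' Fit the static size-density allometry (hierarchical Gaussian model)
#'
#' Fits `log N ~ log D + covariate` with plot-level random intercepts on
#' control-plot observations: the classical static self-thinning
#' allometry with a climate modifier of its intercept. The covariate is
#' centered (MAT, VPD) or centered and scaled (P, AHMI) on the fitting
#' data; constants are stored for prediction. Estimation is by REML
#' (lme4); joint uncertainty draws for the fixed effects are sampled
#' from the asymptotic normal of the estimator so that downstream
#' derived quantities can be propagated draw-wise.
#'
#' @param data data.frame with columns `plot_id`, `D` (cm, QMD),
#'   `N` (trees/ha) and the covariate column.
#' @param covariate covariate column name (e.g. `"mat_longterm"`).
#' @param scheme transform scheme for the covariate.
#' @param center optional centering constant; defaults to the
#'   fitting-dataset mean.
#' @param n_draws number of fixed-effect draws.
#' @param seed seed for the draws.
#' @return object of class `static_fit`: coefficients `alpha0`, `alpha1`,
#'   `alpha2`, `sigma_alpha0`, `sigma`, the plot intercepts, a `draws`
#'   data.frame (`alpha0, alpha1, alpha2`), and the covariate transform.
#' @export
fit_static <- function(data, covariate = "mat_longterm",
                       scheme = c("center", "center_scale", "none"),
                       center = NULL, n_draws = 1000, seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(all(c("plot_id", "D", "N", covariate) %in% names(data)))
  if (length(unique(data$plot_id)) < 2L) {
    stop("fit_static: need >= 2 plots to identify the plot random effect")
  }
  if (any(data$D <= 0) || any(data$N <= 0)) {
    stop("fit_static: non-positive D or N")
  }
  tr <- transform_covariate(data[[covariate]], scheme, center = center)
  df <- data.frame(logN = log(data$N), logD = log(data$D),
                   cov_c = tr$values, plot_id = factor(data$plot_id))
  fit <- lme4::lmer(logN ~ logD + cov_c + (1 | plot_id), data = df,
                    REML = TRUE)
  fe <- lme4::fixef(fit)
  vc <- as.matrix(stats::vcov(fit))
  set.seed(seed)
  draws <- MASS::mvrnorm(n_draws, mu = fe, Sigma = vc)
  colnames(draws) <- c("alpha0", "alpha1", "alpha2")
  vr <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    alpha0 = unname(fe[1]), alpha1 = unname(fe[2]), alpha2 = unname(fe[3]),
    sigma_alpha0 = vr$sdcor[vr$grp == "plot_id"],
    sigma = vr$sdcor[vr$grp == "Residual"],
    plot_intercepts = lme4::ranef(fit)$plot_id[, 1],
    draws = as.data.frame(draws),
    covariate = covariate, transform = tr[c("center", "scale", "scheme")],
    n_obs = nrow(df), n_plots = nlevels(df$plot_id), model = fit),
    class = "static_fit")
}

#' @method print static_fit
#' @export
print.static_fit <- function(x, ...) {
  cat("Static self-thinning allometry (", x$n_obs, " obs, ", x$n_plots,
      " plots)\n", sep = "")
  cat(sprintf("  log N = %.3f %+.3f log D %+.4f (%s - %.3f)\n",
              x$alpha0, x$alpha1, x$alpha2, x$covariate,
              x$transform$center))
  cat(sprintf("  sigma_plot = %.3f, sigma = %.3f\n", x$sigma_alpha0,
              x$sigma))
  invisible(x)
}

#' Predict maximum log density from a static fit
#'
#' `mu = alpha0 + alpha1 log D + alpha2 (cov - center)`, with a 95%
#' interval obtained draw-wise.
#'
#' @param fit a `static_fit`.
#' @param D QMD (cm), > 0 (vectorized).
#' @param covariate_value covariate on its original scale; defaults to
#'   the dataset center (so the climate term vanishes).
#' @return data.frame `D, mean, lower, upper` in log trees/ha.
#' @export
predict_max_log_density <- function(fit, D, covariate_value = NULL) {
  stopifnot(inherits(fit, "static_fit"))
  if (any(D <= 0)) stop("predict_max_log_density: D must be > 0")
  cov_c <- if (is.null(covariate_value)) 0 else
    (covariate_value - fit$transform$center) / fit$transform$scale
  dr <- fit$draws
  out <- lapply(D, function(d) {
    v <- dr$alpha0 + dr$alpha1 * log(d) + dr$alpha2 * cov_c
    c(mean = fit$alpha0 + fit$alpha1 * log(d) + fit$alpha2 * cov_c,
      lower = stats::quantile(v, 0.025, names = FALSE),
      upper = stats::quantile(v, 0.975, names = FALSE))
  })
  cbind(data.frame(D = D), do.call(rbind, out))
}

#' Stand density index: maximum stocking at D = 25 cm
#'
#' The STL-predicted maximum density at the reference QMD of 25 cm.
#' With a negative climate coefficient it decreases by a factor
#' `exp(alpha2)` per unit of (centered) covariate.
#'
#' @param fit a `static_fit`.
#' @param covariate_value covariate on its original scale (default:
#'   dataset center).
#' @return list `mean, lower, upper` in trees/ha.
#' @export
sdi25 <- function(fit, covariate_value = NULL) {
  p <- predict_max_log_density(fit, 25, covariate_value)
  cov_c <- if (is.null(covariate_value)) 0 else
    (covariate_value - fit$transform$center) / fit$transform$scale
  v <- exp(fit$draws$alpha0 + fit$draws$alpha1 * log(25) +
             fit$draws$alpha2 * cov_c)
  list(mean = exp(p$mean), lower = stats::quantile(v, 0.025, names = FALSE),
       upper = stats::quantile(v, 0.975, names = FALSE))
}

#' Simulate observations directly from the static allometry
#'
#' Draws `log N = alpha0j + alpha1 log D + alpha2 cov_c + eps` with plot
#' random intercepts — the model in its generative direction, used for
#' exact-recovery and calibration tests.
#'
#' @param n_plots number of plots.
#' @param obs_per_plot observations per plot.
#' @param truth list with `alpha0, alpha1, alpha2, sigma_alpha0, sigma`.
#' @param mat_range covariate (MAT) spatial range.
#' @param mat_center centering constant used in the generative mean.
#' @param d_range QMD range sampled log-uniformly.
#' @param seed seed.
#' @return data.frame `plot_id, D, N, mat_longterm`.
#' @export
simulate_static_data <- function(n_plots = 40, obs_per_plot = 8,
                                 truth = truth_params(),
                                 mat_range = c(9.5, 12.5), mat_center = 11,
                                 d_range = c(10, 100), seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_plots), function(j) {
    mat <- stats::runif(1, mat_range[1], mat_range[2])
    a0j <- stats::rnorm(1, truth$alpha0, truth$sigma_alpha0)
    D <- exp(stats::runif(obs_per_plot, log(d_range[1]), log(d_range[2])))
    logN <- a0j + truth$alpha1 * log(D) +
      truth$alpha2 * (mat - mat_center) +
      stats::rnorm(obs_per_plot, 0, truth$sigma)
    data.frame(plot_id = plot_label(j), D = D, N = exp(logN),
               mat_longterm = mat, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
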