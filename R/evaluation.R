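#' Goodness-of-fit metrics
#'
#' `R2 = 1 - SSE/SST`, `RMSE = sqrt(SSE/n)`, `BIAS = sum(y - yhat)/n`.
#' With out-of-sample predictions R2 can be negative; with a
#' zero-variance response it is undefined and flagged rather than
#' silently NaN.
#'
#' @param y observed values.
#' @param yhat predicted values, same length.
#' @param response_label label recorded in the report.
#' @return list of class `metric_report`: `r2, rmse, bias, n,
#'   response_label, r2_defined`.
#' @export
compute_metrics <- function(y, yhat, response_label = "response") {
  if (length(y) != length(yhat)) stop("compute_metrics: length mismatch")
  if (length(y) < 2L) stop("compute_metrics: need >= 2 observations")
  sse <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  structure(list(
    r2 = if (sst > 0) 1 - sse / sst else NA_real_,
    rmse = sqrt(sse / length(y)),
    bias = sum(y - yhat) / length(y),
    n = length(y), response_label = response_label,
    r2_defined = sst > 0), class = "metric_report")
}

#' @method print metric_report
#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("%s (n = %d): R2 = %s, RMSE = %.4g, bias = %.4g\n",
              x$response_label, x$n,
              if (x$r2_defined) sprintf("%.3f", x$r2) else "undefined",
              x$rmse, x$bias))
  invisible(x)
}

#' Leave-one-plot-out cross-validation
#'
#' Refits the chosen model once per plot on all remaining plots and
#' predicts the held-out plot with the random effect at its population
#' mean (the only defensible choice for a never-seen plot). Metrics are
#' pooled over all out-of-sample predictions. The static model is
#' evaluated on log N; the mortality models on the dead-tree count, the
#' count per hectare, and the per-tree rate.
#'
#' @param data for `model = "static"` a data.frame as in [fit_static()];
#'   otherwise a periods table as in [fit_mortality()] (with `area_m2`).
#' @param model `"static"`, `"composite"` or `"spacetime"`.
#' @param covariate static-model covariate column.
#' @param ... passed to the underlying fit function.
#' @return list with `pooled` (one or three `metric_report`s), `folds`
#'   (per-fold n), and `n_refits`.
#' @export
loo_plot_cv <- function(data, model = c("static", "composite", "spacetime"),
                        covariate = "mat_longterm", ...) {
  model <- match.arg(model)
  plots <- unique(data$plot_id)
  if (length(plots) < 3L) stop("loo_plot_cv: need >= 3 plots")
  obs <- NULL; pred <- NULL; fold_n <- integer(0)
  per_ha <- NULL; rate_obs <- NULL; rate_pred <- NULL; per_ha_pred <- NULL
  for (p in plots) {
    train <- data[data$plot_id != p, , drop = FALSE]
    test <- data[data$plot_id == p, , drop = FALSE]
    if (model == "static") {
      f <- fit_static(train, covariate = covariate, n_draws = 200, ...)
      cov_c <- (test[[covariate]] - f$transform$center) / f$transform$scale
      yhat <- f$alpha0 + f$alpha1 * log(test$D) + f$alpha2 * cov_c
      obs <- c(obs, log(test$N)); pred <- c(pred, yhat)
    } else {
      f <- fit_mortality(train, variant = model, n_draws = 200, ...)
      mu <- exp(linear_predictor(
        f, test$D_start, test$N_start, test$delta_D, test$N_raw_start,
        mat_longterm_c = test$mat_longterm - f$mat_center,
        mat_anomaly = test$mat_anomaly,
        mat_period_c = test$mat_period - f$mat_center,
        variant = f$variant))
      obs <- c(obs, test$delta_N); pred <- c(pred, mu)
      area_ha <- test$area_m2 / 1e4
      per_ha <- c(per_ha, test$delta_N / area_ha)
      per_ha_pred <- c(per_ha_pred, mu / area_ha)
      rate_obs <- c(rate_obs, test$delta_N / test$N_raw_start)
      rate_pred <- c(rate_pred, mu / test$N_raw_start)
    }
    fold_n <- c(fold_n, nrow(test))
  }
  pooled <- if (model == "static") {
    list(logN = compute_metrics(obs, pred, "logN"))
  } else {
    list(count = compute_metrics(obs, pred, "mortality_count"),
         count_per_ha = compute_metrics(per_ha, per_ha_pred,
                                        "mortality_count_per_ha"),
         rate = compute_metrics(rate_obs, rate_pred, "mortality_rate"))
  }
  list(pooled = pooled, folds = data.frame(plot_id = plots, n = fold_n),
       n_refits = length(plots), n_predictions = sum(fold_n))
}
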