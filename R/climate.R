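#' Annual heat-moisture index
#'
#' AHMI = (MAT + 10) / (P / 1000), the inverse of the Martonne aridity
#' index. Higher values indicate more arid conditions; the index increases
#' with temperature and decreases with precipitation.
#'
#' @param mat mean annual temperature (degrees C).
#' @param p annual precipitation (mm), > 0.
#' @return unitless index, vectorized.
#' @examples
#' ahmi(11, 1000) # 21
#' @export
ahmi <- function(mat, p) {
  if (any(is.na(p)) || any(p <= 0)) {
    stop("ahmi: precipitation must be positive")
  }
  (mat + 10) / (p / 1000)
}

#' Long-term plot climate means over a reference window
#'
#' Arithmetic mean of an annual climate variable over the (inclusive)
#' reference window, per plot. The 1960-2000 MAT mean is the spatial
#' covariate of both the static allometry and the mortality models.
#'
#' @param climate data.frame with `plot_id`, `year` and the variable.
#' @param var variable column name (default `"mat"`).
#' @param window inclusive `c(first, last)` calendar-year bounds.
#' @return data.frame `plot_id`, `<var>_longterm`.
#' @export
longterm_mean <- function(climate, var = "mat", window = c(1960, 2000)) {
  stopifnot(all(c("plot_id", "year", var) %in% names(climate)))
  inw <- climate[climate$year >= window[1] & climate$year <= window[2], ]
  miss <- setdiff(unique(climate$plot_id), unique(inw$plot_id))
  if (length(miss) > 0L) {
    stop("longterm_mean: no records inside the reference window for plot(s): ",
         paste(miss, collapse = ", "))
  }
  agg <- tapply(inw[[var]], inw$plot_id, mean)
  out <- data.frame(plot_id = names(agg), v = as.numeric(agg),
                    stringsAsFactors = FALSE)
  names(out)[2] <- paste0(var, "_longterm")
  out
}

#' Period climate: duration-weighted mean of annual values
#'
#' The climate of an intercensus period is the mean of the annual values
#' of the calendar years overlapping the period, weighted by the overlap
#' of each year interval `[y, y+1)` with `[start, end]`.
#'
#' @param years calendar years of the annual series.
#' @param values annual values aligned with `years`.
#' @param start,end decimal-year period bounds, `end > start`.
#' @return scalar weighted mean.
#' @export
period_mean <- function(years, values, start, end) {
  stopifnot(end > start)
  need <- seq.int(floor(start), ceiling(end) - 1L)
  missing_years <- setdiff(need, years)
  if (length(missing_years) > 0L) {
    stop("period_mean: climate series missing year(s): ",
         paste(missing_years, collapse = ", "))
  }
  w <- pmin(need + 1, end) - pmax(need, start)
  v <- values[match(need, years)]
  sum(w * v) / sum(w)
}

#' Attach climate covariates to intercensus periods
#'
#' Adds, per period: the plot's long-term MAT (`mat_longterm`), the
#' period MAT (`mat_period`, duration-weighted), the anomaly
#' (`mat_anomaly = mat_period - mat_longterm`, so the decomposition is
#' exact by construction), precipitation, AHMI, and VPD when available.
#'
#' @param periods periods table with `plot_id`, `start`, `end`.
#' @param climate data.frame `plot_id`, `year`, `mat`, `precip`,
#'   optionally `vpd` (VPD rows may be absent/NA before 1980).
#' @param window reference window for the long-term mean.
#' @return `periods` with covariate columns appended.
#' @export
build_covariates <- function(periods, climate, window = c(1960, 2000)) {
  lt <- longterm_mean(climate, "mat", window)
  periods$mat_longterm <- lt$mat_longterm[match(periods$plot_id, lt$plot_id)]
  per_var <- function(var) {
    vapply(seq_len(nrow(periods)), function(i) {
      cl <- climate[climate$plot_id == periods$plot_id[i], ]
      ok <- !is.na(cl[[var]])
      if (!any(ok)) return(NA_real_)
      tryCatch(period_mean(cl$year[ok], cl[[var]][ok],
                           periods$start[i], periods$end[i]),
               error = function(e) NA_real_)
    }, numeric(1))
  }
  periods$mat_period <- vapply(seq_len(nrow(periods)), function(i) {
    cl <- climate[climate$plot_id == periods$plot_id[i], ]
    period_mean(cl$year, cl$mat, periods$start[i], periods$end[i])
  }, numeric(1))
  periods$mat_anomaly <- periods$mat_period - periods$mat_longterm
  periods$precip <- per_var("precip")
  periods$ahmi <- ahmi(periods$mat_period, periods$precip)
  periods$vpd <- if ("vpd" %in% names(climate)) per_var("vpd") else NA_real_
  periods$year_mid <- (periods$start + periods$end) / 2
  periods
}

#' Center / center-and-scale a covariate, keeping the constants
#'
#' MAT and VPD are centered; precipitation and AHMI are centered and
#' scaled. Constants are computed on the fitting dataset and stored so
#' the transform is invertible and applicable to new data. The scale is
#' the sample (n-1) standard deviation.
#'
#' @param x numeric vector.
#' @param scheme one of `"center"`, `"center_scale"`, `"none"`.
#' @param center,scale optional pre-computed constants (for new data).
#' @return list with `values`, `center`, `scale`, `scheme`.
#' @export
transform_covariate <- function(x, scheme = c("center", "center_scale", "none"),
                                center = NULL, scale = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "none") {
    return(list(values = x, center = 0, scale = 1, scheme = scheme))
  }
  if (is.null(center)) center <- mean(x)
  if (scheme == "center") {
    return(list(values = x - center, center = center, scale = 1,
                scheme = scheme))
  }
  if (is.null(scale)) scale <- stats::sd(x)
  if (!is.finite(scale) || scale == 0) {
    stop("transform_covariate: zero variance, cannot center_scale")
  }
  list(values = (x - center) / scale, center = center, scale = scale,
       scheme = scheme)
}

#' Invert a covariate transform
#' @param values transformed values.
#' @param transform the list returned by [transform_covariate()].
#' @return values on the original scale.
#' @export
untransform_covariate <- function(values, transform) {
  values * transform$scale + transform$center
}
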