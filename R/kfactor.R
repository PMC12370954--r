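#' Extract mortality events for the k-factor analysis
#'
#' A mortality event is an intercensus period with a recorded dead-tree
#' QMD. Events with few deaths carry a very noisy QMD ratio, so only
#' events with strictly more than `min_dead` dead trees are retained.
#' The k factor of an event is `D_dead / D_live_start`; values below 1
#' mean the trees that died were smaller than their neighbours
#' (suppressed).
#'
#' @param periods periods table with `delta_N`, `D_dead`, `D_start` and
#'   covariates.
#' @param min_dead exclusive threshold (default 3: an event needs more
#'   than three dead trees).
#' @return data.frame of events (`plot_id, n_dead, D_live_start,
#'   D_dead_end, k`, plus any of `mat_period, mat_longterm, precip,
#'   ahmi, year_mid, ho` present); events with deaths but a missing dead
#'   QMD are skipped and counted in `attr(, "skipped")`.
#' @export
extract_events <- function(periods, min_dead = 3) {
  eligible <- periods$delta_N > min_dead
  skipped <- sum(eligible & is.na(periods$D_dead))
  keep <- eligible & !is.na(periods$D_dead)
  ev <- periods[keep, , drop = FALSE]
  out <- data.frame(plot_id = ev$plot_id, n_dead = ev$delta_N,
                    D_live_start = ev$D_start, D_dead_end = ev$D_dead,
                    k = ev$D_dead / ev$D_start, stringsAsFactors = FALSE)
  for (nm in c("mat_period", "mat_longterm", "precip", "ahmi", "year_mid",
               "ho")) {
    if (nm %in% names(ev)) out[[nm]] <- ev[[nm]]
  }
  attr(out, "skipped") <- skipped
  out
}

#' Pooled k-factor estimate
#'
#' Zero-intercept least-squares regression of the dead-tree QMD on the
#' live-tree QMD across events; the slope is the pooled dead/live size
#' ratio (consistent with k being defined as a ratio and with the 1:1
#' reference line). An intercept variant is available for diagnostics.
#'
#' @param events data.frame from [extract_events()].
#' @param intercept include a free intercept (default FALSE).
#' @return list `slope, lower, upper, n`, plus `intercept` when fitted.
#' @export
fit_k <- function(events, intercept = FALSE) {
  if (nrow(events) < 2L) stop("fit_k: need >= 2 events")
  if (all(events$D_live_start == 0)) stop("fit_k: degenerate D_live")
  fml <- if (intercept) D_dead_end ~ D_live_start else
    D_dead_end ~ 0 + D_live_start
  m <- stats::lm(fml, data = events)
  ci <- stats::confint(m)["D_live_start", ]
  out <- list(slope = unname(stats::coef(m)["D_live_start"]),
              lower = unname(ci[1]), upper = unname(ci[2]),
              n = nrow(events))
  if (intercept) out$intercept <- unname(stats::coef(m)["(Intercept)"])
  out
}

#' Test covariate effects on the k factor
#'
#' Linear mixed model `k ~ covariate` with a plot-level random
#' intercept, one covariate at a time (climate: MAT, precipitation,
#' AHMI; temporal trend: calendar year; structure: dominant height Ho).
#' Reports Wald 95% intervals and whether each covers zero.
#'
#' @param events data.frame from [extract_events()].
#' @param covariates covariate column names to test (silently skipping
#'   absent ones is an error; constant columns are flagged, not tested).
#' @return data.frame `covariate, estimate, lower, upper, covers_zero,
#'   note`.
#' @export
test_k_covariates <- function(events,
                              covariates = c("mat_period", "precip",
                                             "ahmi", "year_mid")) {
  if (length(unique(events$plot_id)) < 2L) {
    stop("test_k_covariates: need >= 2 plots for the plot random effect")
  }
  missing_cov <- setdiff(covariates, names(events))
  if (length(missing_cov) > 0L) {
    stop("test_k_covariates: covariate(s) not in events: ",
         paste(missing_cov, collapse = ", "))
  }
  rows <- lapply(covariates, function(nm) {
    x <- events[[nm]]
    if (length(unique(x[!is.na(x)])) < 2L) {
      return(data.frame(covariate = nm, estimate = NA_real_,
                        lower = NA_real_, upper = NA_real_,
                        covers_zero = NA, note = "constant covariate",
                        stringsAsFactors = FALSE))
    }
    df <- data.frame(k = events$k, x = scale(x, scale = FALSE),
                     plot_id = factor(events$plot_id))
    df <- df[stats::complete.cases(df), ]
    m <- lme4::lmer(k ~ x + (1 | plot_id), data = df, REML = TRUE)
    est <- lme4::fixef(m)["x"]
    se <- sqrt(stats::vcov(m)["x", "x"])
    lo <- est - 1.96 * se
    hi <- est + 1.96 * se
    data.frame(covariate = nm, estimate = unname(est), lower = unname(lo),
               upper = unname(hi), covers_zero = lo <= 0 && hi >= 0,
               note = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
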