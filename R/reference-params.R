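#' Reference parameter estimates for mountain ash self-thinning models
#'
#' Published posterior-mean parameter summaries for the static size-density
#' allometry and the two growth-mortality allocation models fitted to the
#' long-term Eucalyptus regnans silvicultural-experiment network of
#' Victoria's Central Highlands (1947-2000). These are the package's default
#' generator truth values and the inputs to its worked examples: the
#' self-thinning line and the climate effect sizes are *derived* from them
#' at run time, never stored.
#'
#' Structure:
#' \describe{
#'   \item{static}{`alpha0` (STL intercept, log trees/ha), `alpha1`
#'     (slope on log D), `alpha2` (per-degree MAT effect), `sigma_alpha0`
#'     (plot-level SD), `sigma` (residual SD).}
#'   \item{eq_spacetime}{NB mortality model with the MAT space/time
#'     decomposition: `beta0` intercept, `beta1` on log D, `beta2` on
#'     log N, `beta3` on long-term MAT, `beta4` on the MAT anomaly,
#'     `sigma_beta0` plot SD, `theta` NB shape.}
#'   \item{eq_composite}{NB mortality model with the composite period MAT:
#'     `beta5` replaces `beta3`/`beta4`.}
#'   \item{k_factor}{pooled dead/live QMD ratio.}
#'   \item{carbon}{typical-stand carbon density (t C/ha), tall-open wet
#'     forest extent (ha), and the car-commute equivalence constants
#'     (g C/km, km/yr, yr).}
#'   \item{climate}{dataset mean MAT (deg C, the centering constant),
#'     spatial MAT range, observed warming over 1947-2000 (deg C), and the
#'     projected warming by ~2080 under a high-emission scenario (deg C).}
#' }
#' @return nested named list (see Details).
#' @export
mountain_ash_params <- function() {
  list(
    static = list(alpha0 = 12.29, alpha1 = -1.67, alpha2 = -0.09,
                  sigma_alpha0 = 0.12, sigma = 0.06),
    eq_spacetime = list(beta0 = -29.38, beta1 = 2.92, beta2 = 2.38,
                        beta3 = 0.15, beta4 = 0.28,
                        sigma_beta0 = 0.84, theta = 9.39),
    eq_composite = list(beta0 = -29.61, beta1 = 2.95, beta2 = 2.40,
                        beta5 = 0.22, sigma_beta0 = 0.84, theta = 9.42),
    k_factor = 0.62,
    carbon = list(carbon_per_ha = 450, area_ha = 1e6,
                  car_g_per_km = 146, km_per_yr = 1e4, years = 75),
    climate = list(mat_center = 11, mat_range = c(9.5, 12.5),
                   warming_1947_2000 = 0.71, warming_2080 = 3)
  )
}
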