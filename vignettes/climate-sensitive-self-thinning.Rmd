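---
title: "Climate-sensitive self-thinning: models, generator, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Climate-sensitive self-thinning: models, generator, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfthin)
```

## The scientific problem

In an even-aged stand, the self-thinning line (STL) is the upper boundary
of tree density as a function of mean tree size: stands that reach it shed
their smallest members as the survivors grow. On log scales the line is

$$\log N = \text{intercept} + \text{slope} \cdot \log D,$$

with $N$ in trees ha$^{-1}$ and $D$ the quadratic mean diameter (QMD, cm).
The line's height is the forest's *carrying capacity*. If a warming climate
lowers it, stands sitting on the line become overstocked and lose trees —
and carbon — even though nothing happened to them locally. `selfthin`
implements two complementary estimators of the line and its climate
sensitivity, a mortality-based projection machinery, an analysis of which
trees die, and a synthetic stand-dynamics generator that makes every stage
testable against known truth.

## The two model families

**Static allometry.** On unthinned control plots, observed size-density
pairs trace the line directly:

$$\log N_{ij} \sim \mathcal N(\alpha_{0j} + \alpha_1 \log D_{ij} +
\alpha_2\,\mathrm{MAT}_{1960\text{-}2000,j},\ \sigma), \qquad
\alpha_{0j} \sim \mathcal N(\alpha_0, \sigma_{\alpha_0}).$$

$\alpha_2$ (per degree C) moves the intercept with the plot's long-term
mean annual temperature; the plot random intercept absorbs everything
else that differs among sites. Static fits have no temporal resolution:
they integrate the stand's whole history, which is why the dynamic
family exists.

**Growth-mortality allocation.** Between two censuses, the number of
dead trees $\Delta N$ is modelled as negative binomial with a log link:

$$\log \mu_{ij} = \beta_{0ij} + \beta_1 \log D_{ij} + \beta_2 \log N_{ij}
+ \log \Delta D_{ij} + \log N_{\mathrm{raw},ij},$$

where the QMD increment $\Delta D$ and the live count $N_\mathrm{raw}$
enter as offsets with coefficient exactly 1: mortality is proportional
to how much the survivors grew and to how many trees were at risk, so
$\mu / N_\mathrm{raw}$ is an area-free per-tree rate. Climate enters the
intercept either decomposed (spatial long-term MAT via $\beta_3$,
temporal anomaly via $\beta_4$ — the decomposition that tests
space-for-time substitution) or as the composite period MAT ($\beta_5$).
The STL is the stationary trajectory of this process:

$$\text{intercept} = \frac{\beta_0}{-\beta_2} +
\frac{\log \beta_2 - \log(\beta_1 + 1)}{-\beta_2}, \qquad
\text{slope} = \frac{1 + \beta_1}{-\beta_2},$$

and a climate coefficient $\beta_k$ shifts the intercept by
$\beta_k / (-\beta_2)$ per degree. The log terms in the intercept are
small but are kept exactly; `test-derived.R` verifies algebraically that
a stand on the line has a local trajectory slope equal to the line slope
at every size, which is the sense in which the closed forms invert the
mortality model.

## Estimation backend and uncertainty draws

Both families are estimated by (restricted) maximum likelihood —
`lme4::lmer` for the Gaussian LMM and `glmmTMB` (NB2 family) for the
count GLMM. We chose the likelihood route over MCMC because the package's
testing strategy leans on many repeated fits (parameter-recovery
replicates and leave-one-plot-out refits) that must run quickly and
deterministically on a single CPU; at the sample sizes involved (hundreds
to ~1600 periods) the likelihood surface is well behaved and weakly
informative priors would be overwhelmed by the data.

Derived quantities still need joint uncertainty, so every fit carries
*draws*: samples from the asymptotic multivariate normal of the estimator
(on the log scale for the NB shape $\theta$ and the random-effect SD).
`propagate()` applies any transform draw-wise and summarizes by the mean
and central 95% interval — never by transforming summary means, which
would be wrong for nonlinear maps such as
$e^{\beta_5/-\beta_2 \cdot \Delta T}$ (the Jensen gap is asserted in the
tests). Fits gate on the optimizer's convergence code and a positive
definite Hessian and error otherwise.

## The synthetic generator

`gen_dataset()` emulates the structure of a long-term silvicultural
experiment network in mountain ash forest: 112 plots (40 unthinned
controls) of 400-8000 m$^2$ (right-skewed, mean $\approx$ 2600 m$^2$),
censused every 2-3 years inside 1947-2000, on a spatial MAT gradient of
9.5-12.5 °C with a linear warming trend of 0.71 °C over the record,
interannual anomalies (SD 0.45 °C, a typical interannual variability for
the region and consistent with year-to-year swings of about a degree),
annual rainfall 1000-1600 mm, and VPD affine in MAT with noise tuned to
a correlation of ~0.96. Truth parameters default to the published
posterior means (`mountain_ash_params()`), so recovery tests target
realistic values, including the large plot-level intercept SD of 0.84.

Stands initialize at 55-75% of their line density and converge onto the
line; each period draws a QMD increment from the growth submodel

$$g = g_{\max} e^{-D/D_{\text{scale}}} (1 - c\, N / N_{\max}(D)),$$

($g_{\max} = 1.2$ cm yr$^{-1}$, $D_{\text{scale}} = 80$ cm, $c = 0.5$,
lognormal noise SD 0.15) — growth slows with size and as the stand
approaches its line. The mortality draw is NB at the model's own mean,
truncated at the live count; the truncation is ignored when fitting
because its mass is negligible at realistic means (the tests measure
well under one truncated draw per thousand periods). Censusing stops
below 5 live trees. Non-control plots receive a single mid-rotation
removal of 30% of stems — a placeholder schedule, since real experiments
varied; removals are bookkept separately and never counted as deaths.
Dead trees are summarized per period as a dead QMD
$k_{\text{true}} D \exp(\mathcal N(0, 0.1))$ with $k_{\text{true}} =
0.62$, because only the QMD ratio enters the k-factor analysis.

Per-plot random substreams are derived from the master seed, so enlarging
the network does not reshuffle existing plots. A per-tree inventory
expansion (`tree_level = TRUE`) reconstructs a tree list consistent with
the period summaries — the smallest trees die, removals are random,
survivors rescale to the next QMD — and is used to round-trip the
inventory-processing interface exactly; it is intended for small
configurations, not the full network.

**What the generator does not emulate:** spatial tree competition,
disturbance (fire, psyllids, storms), ingrowth, measurement error in
DBH, species mixtures, and any feedback of climate on growth (climate
acts only through mortality). Passing recovery tests therefore shows the
inference machinery is correct *for data of this structure*, not that
the fitted values would reproduce field estimates.

## Inventory processing and selection rules

`build_periods()` pairs successive censuses per plot, counting deaths
and removals separately and computing $\Delta D$ from the live trees at
each census — including recruits of the next census would be impossible
here (the generator has none), and for real data the choice between
live-tree and survivor-only QMD is left explicit rather than guessed;
live trees at each census is what is implemented. Filters retain a
period iff plot area $\ge$ 400 m$^2$, interval $\ge$ 0.5 yr, annualized
$\Delta D \ge$ 0.1 cm yr$^{-1}$, target-species basal-area share
$\ge$ 80%, and the plot is not flagged disturbed (disturbance is an
input flag, never inferred). Retention is a conjunction, hence
order-independent; every exclusion is logged with its reasons. Control
plots are those that never record a removal; the static model uses only
those, while the mortality models use all retained periods — thinned
plots' between-thinning dynamics are informative and widen the density
range, and a configuration switch can restrict them if desired.

## Covariates and transforms

Period climate is the duration-weighted mean of annual values
overlapping the period (the sub-annual alignment is not specified by any
source; duration weighting is the neutral choice). The anomaly is
defined as period MAT minus the plot's 1960-2000 mean, so
`mat_longterm + mat_anomaly == mat_period` holds to machine precision by
construction. MAT and VPD are centered; precipitation and AHMI
($(\mathrm{MAT}+10)/(P/1000)$) are centered and scaled, using the sample
(n-1) SD, recorded in the fit for inversion and prediction on new data.
The default MAT center for the generator's truth is 11 °C, the gradient
midpoint. VPD is carried only from 1980 on, with no imputation.

## Projections and trajectories

`project_warming()` turns the per-degree intercept effect into a
capacity multiplier $e^{\text{effect}\cdot\Delta T}$, draw-wise when a
fit is supplied. `carbon_impact()` scales a fractional decline over an
estate (defaults: 450 t C ha$^{-1}$, 10$^6$ ha) and reports the loss,
the equivalent mature-forest area, and a car-commute equivalence
(146 g C km$^{-1}$, 10,000 km yr$^{-1}$, 75 yr).

`simulate_trajectory()` iterates growth and mortality for one stand
under a baseline, a transient (+$\Delta T$ inside a window), or a
permanent (+$\Delta T$ from an onset) scenario, in deterministic
(expected-mortality) or stochastic mode. Scenario shifts act on the
period MAT — the composite-model mapping; under the space/time
decomposition the conceptually faithful mapping sends a heatwave through
the anomaly coefficient and warming through the long-term mean, and both
coefficients are available from the spacetime fit for that purpose.
Trajectories are compared *in the size-density plane* (log N at matched
D, via `trajectory_logN_at()`): that is how self-thinning diagrams are
read, and it is robust to the slight timing differences that make
same-age comparisons converge only slowly. The tests verify that a
permanent +3 °C run settles within 5% of the baseline density times the
closed-form multiplier, and that a transient run returns to within 0.02
log-density units of the baseline curve.

## k factor

`extract_events()` keeps periods with strictly more than three dead
trees (few-death events carry very noisy QMD ratios); `fit_k()` is a
zero-intercept regression of dead QMD on live QMD — consistent with k
being a ratio and with the 1:1 reference line; a free-intercept variant
exists behind a flag for diagnostics. Covariate tests are linear mixed
models `k ~ covariate` with a plot random intercept, one covariate at a
time. Dominant height is defined, when heights exist, as the mean height
of the 100 largest-diameter trees per ha; the synthetic data carries no
heights, so the column is simply absent there.

## Cross-validation

`loo_plot_cv()` holds out whole plots, refits, and predicts the held-out
plot with the random effect at its population mean — a never-seen plot
admits no other choice. Mortality is scored as count, count per hectare,
and per-tree rate. Out-of-sample R$^2$ can be negative; the optimism
direction (out-of-sample $\le$ in-sample) is asserted on fixtures.

## Problem sizes and numerical choices

The test suite uses 10-40 plot networks for most checks, the full
112-plot network for the coverage study (10 replicates, Wald intervals
from the GLMM) and the k-factor recovery (500 events), 20,000 draws for
propagation closed-form checks, and enumeration to 1e-10 for the NB
normalization oracle — sizes chosen so the whole suite completes in a
couple of minutes while keeping Monte Carlo error well below the
asserted tolerances. Ties and degenerate inputs error loudly rather
than propagate: empty diameter vectors, non-positive DBH/area/`delta_D`,
single-plot random effects, zero-variance covariates under scaling,
zero-variance responses for R$^2$, and transforms undefined on any draw.

## Known limitations

* The static fit applied to full dynamic trajectories (as in
  `analysis/02`) recovers a shallower slope than the truth line, because
  observed states lie *near*, not on, the boundary — the classical
  limitation of static methods that motivates the allocation model; the
  static recovery tests therefore simulate from the static model itself.
* Wald draws are a normal approximation; at much smaller sample sizes
  than the defaults the intervals for $\theta$ and the RE SD can be
  optimistic.
* The year-effect mortality trend and fire/regeneration dynamics are out
  of scope; $\Delta T$ is a scalar input, not a climate-model raster.
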