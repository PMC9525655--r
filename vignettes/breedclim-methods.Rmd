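---
title: "Methods: climate sensitivity of breeding nursery yields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: climate sensitivity of breeding nursery yields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Multi-site wheat performance nurseries grow an annually refreshed set of
advanced breeding lines next to a constant check variety, at the same sites,
in the same seasons. Both therefore experience identical weather, and the
contrast between their estimated climate sensitivities isolates what
breeding progress has done to climate resilience — free of the confounding
that arises when old and new varieties are observed in different years.
`breedclim` turns that design into a pipeline: thermal exposure indices from
daily weather, percentile genotype series from trial entries, fixed-effects
panel regressions of log yield, a warming counterfactual with bootstrap
uncertainty, and a scenario projector.

# Thermal exposure indices

## Hourly disaggregation

Stations report daily extremes only. Hourly temperatures are reconstructed
with a cosine diurnal cycle,

$$T_h = \frac{T_{min}+T_{max}}{2} + (T_{max}-T_{min})\,\frac{\cos(0.2618\,(h-14))}{2},
\qquad h = 1,\dots,24,$$

peaking at 14:00. The constant 0.2618 is used verbatim rather than
recomputed as $2\pi/24 \approx 0.261799$: the difference is below
$2\times10^{-4}$ radians per hour, but pinning the literal constant makes
the curve bit-for-bit reproducible across platforms and against independent
re-implementations. A side effect is that the curve's minimum (at $h=2$,
where the argument is $-0.2618\cdot 12 \approx -\pi$) undershoots $T_{min}$
by at most $(T_{max}-T_{min})(1-\cos(0.2618\cdot12))/2$, a quantifiably tiny
amount that the property tests bound explicitly.

## Degree-day indices

With per-phase thresholds $T_{base} < T_{opt}$ (growth) and $T_{frez}$
(freeze injury), each hour contributes

* **GDD** (growing degree-days): $(T_h - T_{base})/24$ for
  $T_{base} \le T_h \le T_{opt}$, capped at $(T_{opt}-T_{base})/24$ above
  the optimum — useful thermal time saturates rather than grows with heat;
* **EDD** (extreme growing degree-days): $(T_h - T_{opt})/24$ above the
  optimum — damaging heat exposure;
* **FDD** (freezing degree-days): $(T_{frez} - T_h)/24$ at or below the
  freeze threshold — cold exposure (winter kill, late frosts).

Boundary hours ($T_h$ exactly at a threshold) contribute zero in every
branch, so the piecewise definition has no tie-break ambiguity. Days with a
missing extreme produce a marked-missing result, never a silent zero.

## Season windows and phases

Indices accumulate over **fixed calendar windows** per site (average
planting to average harvest month-day), not year-specific phenology. Fixed
windows avoid endogeneity: if the window itself responded to temperature, a
warm season would mechanically shorten its own accumulation. Windows that
wrap December 31 (winter crops) are supported and labelled by **harvest
year**; resolved windows must span 30–365 days.

Because per-trial phenology is rarely recorded in long nursery archives,
growing phases are mapped to fixed **fractions of the window** (a day is
assigned by its mid-day fraction $(i-0.5)/n$). The default is a single
phase covering the whole window; replication-grade analyses should supply
their own per-phase schedule. **Thresholds are mandatory configuration**:
`default_thresholds()` ships $T_{base}=0$, $T_{opt}=17$, $T_{frez}=-5$ °C as
documented placeholders for the synthetic test bed — plausible magnitudes
for a cool-season cereal, but explicitly not a published crop calibration,
and results under them make no replication claim.

`gap_tolerance` (default 0.05) is the maximum fraction of missing days a
season may have and still enter the panel. Strict completeness mirrors the
requirement that yield and climate be paired, without discarding whole
sites over occasional station gaps.

# Genotype series

Within each site-season, breeding-line entries collapse to the 2.5th
(LYG), 50th (MYG), and 97.5th (HYG) percentile yields; the check variety is
carried as CK. Two pinned choices:

* **Percentile definition**: linear interpolation between order statistics
  (type 7 of `stats::quantile()`). At nursery entry counts (tens), the
  percentile convention visibly moves the 2.5/97.5 tails, so the definition
  is explicit and configurable rather than implicit.
* **`min_entries`** (default 5): below this, the tail percentiles collapse
  to the sample extremes and the LYG/HYG series lose meaning; such
  site-seasons are skipped with a message, as are those lacking exactly one
  check entry.

Percentiles are computed per site-season (not pooled per year across
sites), matching the per-trial structure of nursery reporting; the series
always satisfy LYG ≤ MYG ≤ HYG.

# The panel regression

Separately for each genotype class $g \in \{CK, LYG, MYG, HYG\}$:

$$\log(Y_{i,t}) = \alpha_i + \alpha_{1i}\,t + \alpha_{2i}\,t^2 +
\beta\cdot(\mathrm{FDD},\ \mathrm{GDD},\ \mathrm{EDD},\ \mathrm{Prcp},\ \mathrm{Prcp}^2)_{i,t} + \varepsilon_{i,t}.$$

Site intercepts absorb time-invariant differences (soils, management,
elevation); site-specific linear and quadratic trends absorb smooth
non-climate change (agronomy, within-series genetic gain). The climate
coefficients are therefore identified by within-site interannual variation.

Estimation choices:

* **Explicit dummy-variable OLS** rather than a within transformation.
  With at most ~100 sites the design ($3S + 5$ columns) is small, site-
  specific quadratic trends are awkward to demean away, and the projector
  needs the exact $\alpha$'s as baselines. A test verifies that the dummy
  estimator and a residualize-then-regress (Frisch–Waugh) route agree to
  $10^{-8}$.
* $t$ is the season year minus the panel's first year. Centering changes
  trend and intercept estimates, never $\beta$ (verified by a shift-
  invariance property test).
* **Rank handling**: the design is QR-checked up front; rank deficiency is
  an error naming the collinear columns — never a silent pseudo-inverse.
  Identifiability requires ≥ 2 sites and ≥ trend-order + 1 distinct years
  per site.
* **Standard errors** are classical OLS ($\sigma^2 (X'X)^{-1}$), used for
  recovery diagnostics; headline uncertainty comes from the bootstrap, which
  is robust to the error structure the classical formula assumes away.
* **VIF** for the climate block defaults to the *partialled* version: the
  climate columns are residualized on the fixed-effect/trend block first,
  so the diagnostic describes the collinearity that actually afflicts
  $\hat\beta$. The raw within-block version is available via
  `partial = FALSE`; the conditioning set matters and is stated rather than
  left implicit. Perfect collinearity reports `Inf`.

# Warming counterfactual

`perturb_weather()` adds $\Delta t$ to every day's extremes — shifting the
entire hourly curve uniformly — and the indices are recomputed and
differenced per site-season (`warming_deltas()`). Precipitation is never
perturbed. For $\Delta t > 0$, $\Delta(\mathrm{GDD}+\mathrm{EDD}) \ge 0$
and $\Delta \mathrm{FDD} \le 0$ by monotonicity of the hourly pieces.

The point impact averages deltas over site-seasons **before**
exponentiating: with $L = \sum_k \beta_k \overline{\Delta x_k}$, the net
impact is $100\,(e^L - 1)$ %, and each index's component is
$100\,(e^{\beta_k \overline{\Delta x_k}} - 1)$ %. Log-effects are exactly
additive across indices; the percentages are not, which is why both are
returned. The $e^L - 1$ transform is preferred to the first-order $100\,L$
because the response is specified in log yield; at a few percent the two
differ by well under a point, and `transform = "linear"` exposes the
first-order variant for sensitivity checks.

**Bootstrap**: site-seasons are resampled with replacement; each replicate
refits every genotype class on the shared resampled index set (so
genotype-vs-check contrasts are paired) and recomputes the impact, with the
delta means re-weighted by the same resample. The 2.5th/50th/97.5th
percentiles of the replicate distribution give the interval and median.
Published practice is 1000 replicates; the argument is free. Replicates
whose resampled design is singular (e.g. a site left with too few distinct
years for its quadratic trend) are redrawn and counted, with a hard budget
of 50× the requested replicates. The seed is a mandatory argument — no
hidden global randomness. Because the per-site-season deltas are invariant
under resampling (only their weights change), they are computed once and
joined, not recomputed per replicate; with noiseless yields the coefficient
part of the impact is exact, and a constant-delta table then yields a
degenerate (zero-width) interval.

# Scenario projection

For each scenario, climate model, and future year, a genotype's log level
is its **frozen** baseline non-climate level — the baseline-period mean of
$\alpha_i + \alpha_{1i} t + \alpha_{2i} t^2$ over its fitted site-seasons —
plus $\beta_g$ applied to the scenario's site-mean climate. Freezing the
trends confines the projection to climate-driven change: extrapolating
fitted quadratic time trends decades forward would instead assert
continued (accelerating) breeding progress, which the data cannot support.
Changes are expressed relative to the check's baseline log level,
$100\,(e^{\ell_g(y) - \ell^{base}_{CK}} - 1)$ %, and per-period genotype
gains use period-mean log levels within the same scenario and model. Two
self-consistency identities are enforced by test: projecting the baseline
climate reproduces each genotype's historical mean log-yield gain over CK
to $10^{-6}$, and a constant log-offset genotype shows the same gain
($100(e^{0.262}-1) \approx 30$%) in every period.

Default reporting periods are 2030s = 2021–2040, 2050s = 2041–2060,
2090s = 2081–2100; period boundaries are a reporting convention and fully
configurable. Scenario input is either pre-computed site-level season
climate, the linear-warming generator below, or `scenario_from_deltas()` —
a delta-change construction (monthly temperature offsets and precipitation
ratios ramped linearly over the future span, applied to recycled baseline
years). The delta-change reader is a deliberately simple, declared stand-in
for downscaled model output, not a downscaling method; a quadratic
mean-of-squares subtlety applies to $\mathrm{Prcp}^2$, which is averaged as
$\overline{p^2}$ (not $\bar p^2$) on both the baseline and scenario sides
so the self-consistency identity holds exactly.

# The synthetic test bed

`synthetic_config()` fixes the generating conditions once:

* **Weather**: per-site annual sinusoid (site mean drawn from 5–13 °C,
  amplitude 11–15 °C, minimum in mid-January), AR(1) day-to-day noise
  (sd 3 °C, lag-1 correlation 0.6), constant 10 °C diurnal range, wet-day/
  Gamma precipitation. Setting the noise scale to 0 recovers the exact
  sinusoid.
* **Trials**: site-season median log yield follows the fixed-effects model
  exactly, with site intercepts $\mathcal N(8, 0.2)$ (log kg/ha), linear
  trends $\mathcal N(0.008, 0.004)$ per year, tiny quadratic trends, and
  Gaussian log-yield noise (sd 0.12, a typical trial CV). Entries are
  lognormal around the median (so yields stay positive), median-centred so
  MYG recovers the deterministic median exactly at zero dispersion; the
  check sits at `exp(check_offset)` times the median, default
  $\log(1/1.3)$, i.e. the median line ~30% above the check.
* **True coefficients** (log yield per °Cd or mm):
  $\beta_{fdd}=-10^{-3}$, $\beta_{gdd}=2\times10^{-5}$,
  $\beta_{edd}=-8\times10^{-4}$, $\beta_{prcp}=1.5\times10^{-3}$,
  $\beta_{prcp^2}=-7\times10^{-7}$. Under the placeholder thresholds a
  +1 °C counterfactual moves EDD by tens of degree-days per season, so
  these magnitudes were chosen — once, as part of the test-bed design — to
  put the net +1 °C impact at a realistic few-percent decline with a
  harmful EDD component and a beneficial FDD component.
* **Scenarios**: linear-in-year warming applied to recycled baseline years,
  with pseudo climate models perturbing the rate; generated trajectories
  show rising GDD/EDD and falling FDD, verified by a regression sign test.

Everything derives deterministically from one seed (sub-streams offset per
generator, so `gen_weather()` and `gen_trials()` are individually
reproducible).

What the generator does **not** emulate: spatial correlation between sites,
precipitation trends or drought persistence, genotype-specific climate
responses (all four series share one true $\beta$, so genotype contrasts
are null by construction — useful for testing the paired bootstrap, but it
means passing tests say nothing about detecting *differential* resilience),
entry-set turnover structure, or any real geography. Passing recovery tests
demonstrate that the estimator is correct under the model's own
assumptions, not that those assumptions hold in field data.

# Test and simulation sizes

Chosen to exercise each property at meaningful scale: coefficient recovery
uses 200 replicates of a 30-site × 40-year panel (pooled fraction of
coefficients within 3 classical standard errors of truth ≥ 0.99); bootstrap
coverage uses 300 replications of a 12-site × 25-year panel at 200
bootstrap replicates, with nominal-coverage band 93–97%; the degree-day
oracle check enumerates 1000 random threshold/temperature draws at
$10^{-9}$ tolerance. The acceptance script runs a 20-site × 30-year
pipeline with 1000 bootstrap replicates and a two-scenario, three-model
projection.

# Known limitations

* Fixed windows and calendar-fraction phases ignore real phenological
  shifts; the indices are exposure proxies, not development-stage damage
  models.
* Classical standard errors ignore spatial and serial correlation; inference
  should lean on the bootstrap, which resamples site-seasons and therefore
  still assumes independence across site-seasons.
* The projector holds site effects and trends at baseline means: it
  quantifies climate pressure on current genetics, not future breeding.
* No CO₂ fertilization term, no moisture-balance modelling beyond seasonal
  precipitation and its square, and no claim to reproduce any particular
  published calibration under the placeholder thresholds.
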