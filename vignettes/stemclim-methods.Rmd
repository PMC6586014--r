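---
title: "Methods: from stem signals to climate-growth inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from stem signals to climate-growth inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemclim)
```

`stemclim` chains the standard quantitative tools of tree ecophysiology and
dendroecology into one tested pipeline: microclimate derivation, the
zero-growth decomposition of dendrometer records, Gompertz growth phenology,
sap-flow scaling, tree-ring chronology building, bootstrap
principal-component response functions, and climatic-water-deficit
classification of regional growth conditions. This vignette explains each
model, its assumptions, the tunable parameters, and the choices made where
the methods literature leaves the design open.

## Microclimate covariates

Vapour pressure deficit uses the Magnus saturation curve
($e_s = 0.6108\,e^{17.27T/(T+237.3)}$ kPa), so
$\mathrm{VPD} = e_s(T)\,(1 - \mathrm{RH}/100)$. Daily reference
evapotranspiration follows the standard daily Penman--Monteith
formulation (grass reference, soil heat flux $G = 0$, albedo 0.23, net
longwave from the Stefan--Boltzmann estimate with humidity and cloudiness
corrections). Radiation is taken from measured global radiation, not
sunshine hours; when the sub-daily temperature range is unavailable,
`t_min = t_max = t_mean` is a documented degradation. Negative numerators
(rare radiative-loss days) are clipped to zero because reference ET is
physically non-negative.

Monthly potential evapotranspiration for the water-balance classification
uses the Thornthwaite temperature index with solar-geometry daylength by
latitude: month lengths and daylength enter linearly, months at or below
0 °C contribute nothing.

Gap filling is deliberately simple: linear interpolation limited to a
configurable cap (default 6 h at 10-min resolution, i.e. 36 intervals);
precipitation gaps become explicit zeros; every filled span is reported.
A random-forest imputer would be less transparent and imputation quality is
not a claim this package needs to defend.

Elevational extrapolation applies a constant lapse specification
(defaults 0.54 K and 12 mm yr$^{-1}$ per 100 m, the measured local rates
for the kind of inner-alpine transect the package targets). Temperature is
shifted additively; the implied annual precipitation increment is
distributed proportionally over existing events so dry days stay dry, which
makes the operation exactly invertible.

## The zero-growth decomposition

A band dendrometer measures circumference change, converted to radius by
$r = c/2\pi$ and averaged to hourly means (the native 10-min signal carries
sensor noise that the decomposition does not need). The zero-growth model
assumes radial growth happens only at stem water saturation. Operationally:

* the growth line `gro(t)` is the running maximum of the radius up to `t`;
* the tree water deficit `twd(t) = gro(t) - radius(t)` is the reversible,
  drought-related shrinkage below the last maximum.

The decomposition is exact by construction (`radius = gro - twd` to within
one floating-point ulp) and idempotent. Daily summaries report the daily
radius change (difference of consecutive daily *mean* radii --- robust to
diurnal phase, unlike daily maxima; a documented choice), plus the daily
maximum and minimum TWD: the maximum is what climate models respond to, the
minimum is the "close to zero" criterion used to delimit growth.

Growth periods are detected as the longest run of days whose sliding-window
GRO rate (window 5 d) is at least 20 % of the season maximum and whose
daily minimum TWD is at most 30 µm. All three thresholds are arguments;
the published per-site tables of growth periods can always be supplied as a
manual override downstream.

## Gompertz phenology

Seasonal cumulative growth is summarised by the Gompertz sigmoid in its
growth-parameter form,

$$y(t) = A\,\exp\!\big(-\exp\big(\tfrac{\mu e}{A}(\lambda - t) + 1\big)\big),$$

whose parameters are directly the quantities compared across sites and
years: $A$ the total yearly growth (µm), $\mu$ the maximum growth rate
(µm d$^{-1}$), $\lambda$ the lag/onset (DOY). The inflection point is
analytic, $I_p = \lambda + A/(e\mu)$, the curve passes through $A/e$ there
and its slope there is exactly $\mu$ --- all of which the tests verify.
Taking $I_p$ analytically rather than as a numeric argmax keeps it exact
and testable.

Fitting is Levenberg--Marquardt nonlinear least squares with a small
multistart around data-driven initials ($A$ = observed maximum, $\mu$ =
largest daily increment, $\lambda$ = first day above 5 % of maximum) plus
perturbed restarts. The convergence flag is honest: degenerate inputs
(all-zero, too short, zero variance) return `NA` parameters, never a
fabricated fit. Under the study noise level (σ = 20 µm over a 150-day
season) the simulated recovery rate of $A$ within 2 % and $\lambda$ within
2 days is 100/100 seeds.

## Sap-flow scaling

Tissue-heat-balance sensors integrate over the whole sapwood depth and
report flow per unit trunk circumference (kg h$^{-1}$ cm$^{-1}$), so
tree-level flow is rate × effective circumference
$C_\mathrm{eff} = C - 2\pi t_\mathrm{bark}$, with bark + phloem thickness a
required input (there is no defensible hidden default). Two-sensor trees
(N/S) are averaged before scaling; single-sensor timestamps are used as-is
with the sensor count recorded. Night-time negative rates are clipped to
zero and counted. Daily sums use step integration (1 kg ≡ 1 l); days
below 90 % completeness are flagged and excluded from site means, which are
reported with standard errors across trees.

## Tree-ring chronologies

Per-year core averaging, basal area increment
$\mathrm{BAI}_t = \pi(R_t^2 - R_{t-1}^2)$ under the pith assumption
$R_0 = 0$ (so $\sum\mathrm{BAI} = \pi R_n^2$, a conservation law tested on
random series), and two-stage ratio detrending:

1. a modified negative exponential $w = a e^{-bt} + k$ ($a,b > 0$,
   $k \ge 0$), falling back to a non-positive-slope line, then to the
   horizontal mean, whenever the stricter model cannot be fit or predicts
   non-positive widths;
2. a second-difference penalized smoother whose transfer function
   $H(f) = 1/(1 + \lambda(2\sin\pi f)^4)$ is fixed to 50 % response at a
   wavelength of two-thirds of the series length. This is the standard
   frequency-cutoff specification of dendrochronological smoothing splines,
   implemented as a discrete penalized regression because the cutoff then
   maps to $\lambda$ in closed form.

Indices are observed/expected ratios at each stage. Prewhitening fits
AR($p$), $p \le 3$, by maximum likelihood and selects $p$ by AIC; residuals
plus the series mean preserve the level. (Simulation note: AIC picks
$p = 0$ on white noise about 75 % of the time --- its well-known mild
overfitting --- and removes an AR(1) with $\phi = 0.7$ to residual
$|r_1| < 0.1$.) The site chronology is the per-year Tukey biweight robust
mean ($c = 9$, median start, ≤ 10 iterations, returning the median when the
MAD degenerates), with sample depth recorded.

Chronology statistics follow the conventional definitions: mean
sensitivity and first-order autocorrelation on the raw widths (computed
before prewhitening, per the usual table footnote), the mean interseries
correlation $\bar r$ on prewhitened indices over pairwise-common years
(minimum overlap 30 yr), and the derived
$\mathrm{SNR} = N\bar r/(1-\bar r)$ and
$\mathrm{EPS} = N\bar r/(N\bar r + 1 - \bar r)$.

Crossdating QC correlates each prewhitened series, in 50-yr segments
lagged by 25 yr, against the leave-one-out biweight master; segments below
the one-tailed critical $r$ at α = 0.01 are flagged with the best lag in
±10 yr as a dating suggestion.

Ring-width files use the Tucson format with both precision dialects
(0.001 mm / stop mark −9999 and 0.01 mm / stop mark 999) auto-detected on
read; the stop marker is only recognised as the final value of a series, so
a genuine 0.999 mm ring survives.

## Bootstrap response functions

Monthly mean temperature and precipitation totals from the previous June
through the current September (16 months × 2 variables = 32 predictors;
window configurable) are standardized and decomposed into principal
components; components passing the Kaiser rule (eigenvalue > 1;
configurable, 0 retains all) are kept, the standardized chronology is
regressed on their scores, and coefficients are rotated back to the monthly
variables. When every component is retained this reproduces OLS exactly ---
a property the tests check to 10⁻¹⁰.

Uncertainty comes from resampling years with replacement (default
N = 1000, seeded) with percentile confidence intervals; a coefficient is
significant when its interval excludes zero (α = 0.05 static, α = 0.1
moving, the conventional levels). The rotation and retained set are
estimated once on the full sample and held fixed across bootstrap draws,
the classical design for bootstrapped response functions; re-estimating
them inside each draw measurably inflates interval width and makes the
procedure conservative (simulated per-column false-positive rate 0.017
versus 0.050 at nominal 0.05 with the fixed design). Moving analysis slides
a 25-yr window in 1-yr steps (100 common years give 76 windows) and skips
windows whose minimum sample depth falls below five trees when depths are
supplied.

## Climatic-water-deficit upscaling

Annual CWD is precipitation minus annual Thornthwaite PET. Cells whose
annual mean temperature falls below the species' thermal floor (−2.5 °C
for larch) are classed `below-thermal-limit` outright; otherwise two CWD
cut points separate `severely-restricted` (red), `drought-restricted`
(yellow) and `favorable` (green) conditions. The cut points are
calibration outputs, never constants: synthetic transect climates are built
from the station normals (6.6 °C, 528 mm at 1570 m) plus the lapse rates,
and the cuts are placed midway between the CWD of the adjacent sites known
to straddle each colour boundary (red/red/yellow/green/green with
elevation). A warming scenario (uniform ΔT on all months ---
month-specific deltas are not resolvable from an annual scenario ---
and a fractional precipitation change) is applied before classification and
commutes with it.

Monthly normals for the transect cells need a within-year shape the annual
normals do not provide: temperature gets a sinusoid with 8.5 K
half-amplitude peaking in July, precipitation summer-peaked weights
(`1 + 0.8 cos` shape), both typical of the continental-alpine convective
regime. These are fixed package defaults, not tuning knobs.

## The synthetic-data generators

Every generator is a pure function of its arguments and a seed, so all
pipeline tests run against data with known ground truth.

* **Microclimate** (hourly): sinusoidal annual (8.5 K) and diurnal (4 K)
  temperature cycles plus a *centred* AR(1) day-to-day anomaly (sd 2.5 K,
  φ = 0.7) --- centring makes the annual mean match the lapse-derived
  normal exactly, so the elevational structure of the ensemble is exact by
  construction. Precipitation is a two-state daily chain
  (p(wet|dry) = 0.25, p(wet|wet) = 0.55) with gamma amounts (shape 0.7)
  scaled to the site normal; radiation is clear-sky × cloud factor tied to
  wet days; soil water follows a 300-mm single bucket (field capacity 0.35,
  wilting point 0.08 m³ m⁻³, matching ~30 cm soils). Scripted droughts
  suppress rain, pull SWC to a floor within ~5 days, and end with a
  30-mm drought-breaking rain that refills the bucket.
* **Dendrometer**: Gompertz growth (defaults A = 1500 µm, µ = 25 µm d⁻¹,
  λ = DOY 130) deposited during shrink-free night hours, minus diurnal
  shrinkage (10 µm kPa⁻¹ of that day's VPD) and a drought component that
  builds while SWC is below 0.12 m³ m⁻³ (up to 250 µm) and relaxes with a
  1.5-day e-folding time; growth is suppressed while the drought component
  is active, so the zero-growth assumption holds by construction. With
  noise and shrinkage off, the partition recovers TWD ≡ 0 and the annual
  increment equals A to 0.15 %.
* **Sap flow**: daily amplitude $q_{max}\,\mathrm{sat}(PET)\,
  \mathrm{sat}(SWC)$ with Michaelis-type saturations; the high-elevation
  configuration sets the soil term to 1 (no soil limitation). Diurnal bell,
  multiplicative lognormal noise, two sensors with ±10 % gains.
* **Ring widths**: age trend × lognormal signal
  $\exp(\beta\,z(\text{climate}) + \text{common AR(1)} + \text{noise})$,
  with the individual-noise variance set from the target $\bar r$ via
  $\sigma^2_\text{ind} = \sigma^2_\text{common}(1-\bar r)/\bar r$; two
  cores per tree with independent 10 % lognormal core noise. The default
  β(June precipitation) = 0.6 injects the kind of early-summer moisture
  signal the pipeline must recover end to end.

What the generators do *not* emulate --- terrain shading, snow dynamics,
stand competition, disturbance outbreaks, hygroscopic bark artefacts ---
bounds what a passing suite shows: the pipeline's algorithms are correct
and calibrated on data obeying their assumptions; field data can violate
those assumptions in ways synthetic tests cannot certify.

## Numerical choices and problem sizes

Tolerances: the partition identity is asserted at 10⁻¹² µm (one ulp);
noise-free Gompertz recovery at 4 significant digits; OLS equivalence at
10⁻¹⁰; detrending of pure trend at 10⁻⁶. Ties and degeneracies: biweight
falls back to the median at zero MAD; detrending falls back
negexp → line → mean and logs the model used; prewhitening returns constant
input unchanged with a warning; growth-period detection returns an
explicit empty, flagged result when no day qualifies.

Validation sizes are chosen to make the stochastic checks stable without
being wasteful: 1000 random traces against the quadratic running-max
oracle, 100 seeded seasons for Gompertz recovery, 100 null simulations at
200 bootstrap resamples (with 50 seeds for the signal-power check) for the
response function, and a two-site × 40-yr demonstration pipeline for the
determinism check. The same quantities are recomputed from scratch by
`scripts/acceptance.R`.

## Known limitations

Pure AR prewhitening (no MA terms) is an identifiability choice for
century-scale series; regional-curve standardization, pith-offset
estimation and pointer-year analysis are out of scope; the FAO-56
implementation expects 2-m wind and does not model terrain shading; the
classification grid carries pixel size as metadata only and no
cartography is provided.
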