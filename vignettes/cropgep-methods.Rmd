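---
title: "From chamber CO2 traces to spectral models of daily GEP: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From chamber CO2 traces to spectral models of daily GEP: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropgep)
```

# The measurement problem

Gross ecosystem production (GEP) of a crop stand cannot be measured
directly: instruments see only net exchange. A closed dynamic chamber
measures two things in quick succession on the same collar — net
ecosystem production (NEP) under a transparent chamber, and ecosystem
respiration (Reco) under an opaque one — and GEP is recovered as
`GEP = NEP + Reco`. Chamber campaigns are sparse (a dozen field days per
season), so continuous GEP requires a model bridge driven by
continuously logged PAR and temperature. Once daily GEP (`GEP_d`) exists
for the dates when canopy reflectance and leaf area index (LAI) were
also sampled, simple linear spectral models of `GEP_d` can be fitted and
their seasonal stability examined.

This package implements that full chain, with a synthetic-season
generator standing in for the field data so every stage is testable
against known truth.

# Chamber fluxes

Each closure's CO2 mole-fraction trace is fitted by ordinary least
squares against time, and the slope converted to an areal flux:

    F = dC/dt * V / (A * Mv),   Mv = R T / p

with chamber volume `V` (default 0.296 m^3), collar area `A` (default
0.5625 m^2, a 0.75 m square) and the ideal-gas molar volume `Mv` at the
chamber air temperature and pressure. The raw flux is release-positive;
transparent closures are reported as uptake-positive NEP (`NEP =
-F_raw`), opaque ones as release-positive Reco.

Design choices:

* The first 10 s of each trace are discarded by default
  (`trim_s = 10`): placing the chamber perturbs the headspace and the
  analyzer loop needs a few seconds to mix.
* QC excludes fluxes whose concentration fit has r^2 < 0.8, **except**
  that small fluxes (|F| <= 0.5 umol m-2 s-1 by default) are flagged
  `near_zero_review` and retained: a genuinely tiny flux produces a flat,
  noise-dominated trace with low r^2, and dropping those would
  systematically bias low-activity periods (winter, nighttime analogues)
  toward zero records rather than zero fluxes.
* A zero-variance trace is given slope 0 and, by convention, r^2 = 0 so
  it is flagged deterministically rather than producing NaN.

# Flux partitioning and the continuous bridge

For every campaign (one field day) two sub-models are fitted to the
QC-passed fluxes:

* Respiration, Lloyd–Taylor form:
  `Reco(T) = rref * exp(e0 * (1/(Tref - T0) - 1/(T_K - T0)))` with the
  canonical constants `Tref = 283.15 K`, `T0 = 227.13 K`. `rref` is the
  respiration at 10 °C and `e0` (K) the temperature sensitivity. Bounds:
  `rref` in (0, 50], `e0` in [50, 450]. When the day's temperature span
  is under 2 °C the two parameters are not jointly identifiable, so `e0`
  is fixed at 308.56 K and `rref` follows in closed form.
* Light response, rectangular hyperbola (Michaelis–Menten):
  `GEP(PAR) = alpha * PAR * gpmax / (alpha * PAR + gpmax)`, fitted to
  `GEP = NEP + Reco(T)` at the NEP measurement times. Bounds `alpha` in
  (0, 0.3], `gpmax` in (0, 120]; a three-point multi-start
  ((0.02, 15), (0.05, 30), (0.1, 60)) guards against the flat SSE valley
  of the hyperbola, best SSE wins, ties go to the smaller `gpmax`
  because the smaller asymptote is the less extrapolated claim.

Both fits use bounded Levenberg–Marquardt (`minpack.lm::nlsLM`) with
tight convergence tolerances (`ftol = ptol = 1e-14`) so that noiseless
round-trip tests recover parameters to ~1e-6 relative error rather than
solver default precision.

The four parameters are interpolated linearly in time between campaign
anchors placed at 12:00 of each campaign day (campaigns span a whole
field day, so noon is its natural centre), held constant before the
first and after the last campaign. The respiration driver is soil
temperature where available, air temperature otherwise. The continuous
30-min series is then

    gep = light_response(PAR), reco = reco_model(T), nep = gep - reco

which makes `NEP = GEP - Reco` an exact identity of the reconstruction,
not an approximation.

Daily aggregation: `GEP_d` is the sum of the 30-min GEP values whose
step midpoint lies between sunrise and sunset, times 1800 s and
12.011e-6 gC umol-1, reported in gCO2-C m-2 d-1. `PAR_d` is the
arithmetic mean of PAR over the same window. Sunrise and sunset come
from the standard solar-declination approximation
(`decl = 23.45 sin(2 pi (284 + doy)/365)`, hour angle from
`cos H = -tan(lat) tan(decl)`) in local solar time; a PAR-threshold mode
(first/last step above 1 umol m-2 s-1) is available when the driver
series is trusted more than the geometry. Polar latitudes are rejected.

# Spectral indices

Indices are computed either from band reflectances (NDVI, SAVI with
soil factor `L = 0.5` — the canonical mid-cover value — and PRI) or from
raw dual-radiometer readings via
`VI = (Z R1r Y - R2r X) / (Z R1r Y + R2r X)`, where `Z` calibrates the
two reflected channels against each other; with `Z = 1` and equal
incident readings this reduces exactly to the reflectance form (a tested
equivalence). WDRVI is a Möbius transform of NDVI with weight
`alpha = 0.2`, strictly increasing and fixing NDVI = 1, and
`sWDRVI = (WDRVI + 1)/2` rescales it to [0, 1]. The bundled
`seasonal_max_vi()` table of published crop-year maxima is used to
verify that the transform chain reproduces the printed sWDRVI maxima
from the printed NDVI maxima to the printed 2-decimal precision (two
potato entries in the source table are internally inconsistent by more
than printing precision and are documented as such in the test).

# The four GEP_d models and their statistics

`GEP_d` is regressed on (1) LAI, (2) a VI, (3) VI*PAR_d, (4) VI*LAI —
all simple linear models fitted by OLS. Statistics reported per fit:
R^2, RMSE with divisor n (population form), `NRMSE = 100 RMSE / (max -
min)` of the observed `GEP_d` — range normalization, so RMSE/NRMSE pairs
back-calculate to the observed range — and the two-sided slope t-test
p-value. Missing components (LAI, PAR_d, or a VI) drop records pairwise
per model row, so n varies across rows by design. PRI only enters model
2: it is a physiological light-use-efficiency proxy, not a greenness
index, and forming PRI products with LAI has no mechanistic reading.

Validation of a pooled ("general") model applies its coefficients to
each crop separately and reports the observed-vs-predicted regression
and the relative bias `100 (sum(pred) - sum(obs)) / sum(obs)`, flagged
above 25 %.

# Phase analysis

Each crop-year (or pooled multi-year crop dataset) is split into a
vegetative and a reproductive phase at the date of maximum LAI — the
canopy peak is the natural turning point, and a max-`GEP_d` rule and a
manual override are provided for sensitivity checks. The same `GEP_d`
model is fitted in each phase and the slopes compared with a Welch-type
two-sample t-test on regression slopes:
`t = (a1 - a2) / sqrt(se1^2 + se2^2)` with Welch–Satterthwaite degrees
of freedom built from each fit's residual df. Its empirical size is
checked by simulation (equal true slopes, 1000 replicates) to sit in
[0.03, 0.07] at the nominal 0.05.

Light-use efficiency is defined here as
`LUE = GEP_d / (PAR_d * daylength * 1e-6)` — grams of carbon fixed per
mol of *incident* photons over the daylight window; no fAPAR term is
involved, so values are not comparable to absorbed-light LUE.

# The synthetic season generator

The generator emulates a temperate lowland cropland site (52.43° N):

* **Drivers**: PAR follows a half-sinusoid between the solar sunrise and
  sunset, scaled by a clear-sky noon amplitude (1600 umol m-2 s-1 at the
  solstice, following the noon solar elevation through the year) and a
  per-day clearness factor `max(0.2, 1 - |N(0, 0.2)|)`. That yields
  daylight-mean PAR_d around 650–850 umol m-2 s-1 in season with maxima
  just above 1000, the observed magnitude range for such sites. Air
  temperature is a seasonal sinusoid (mean 8 °C, amplitude 10.5 °C)
  plus a 5 °C diurnal cycle and a per-day offset; soil temperature is
  the damped, lagged version.
* **Phenology**: total LAI is piecewise double-logistic — a logistic
  green-up from `lai_start` to exactly `lai_max` at the configured peak
  day, then a logistic decline to a plateau of standing (partly
  senesced) leaf area around 2.5 m^2 m-2. Winter cereals get
  `lai_start` of 1–1.5 (they overwinter as a dense green stand); spring
  crops start from 0. Green LAI equals total LAI until the peak and then
  declines linearly in fraction (default 2 % d-1), separating structure
  from active photosynthetic area.
* **True fluxes**: `gpmax = 15 * greenLAI` (floored at 0.5), calibrated
  so that seasonal `GEP_d` maxima span roughly 10–20 gCO2-C m-2 d-1
  across dry-year and wet-year LAI maxima, the reported field range;
  `alpha = 0.06`; `rref = 2 (1 + 0.5 LAI/LAI_max)` so respiration grows
  modestly with biomass; `e0 = 308.56 K`. Parameter trajectories between
  campaign anchors use the *same* linear-interpolation convention as the
  partitioning stage, and campaign-day closures are simulated with that
  day's anchor values held constant across the day (within-day parameter
  drift at a 14-day campaign interval is a sub-0.1 % effect). This makes
  the zero-noise chain an exact round trip, which is what the round-trip
  tests rely on.
* **Closures**: 5–12 transparent/opaque pairs per campaign day (count
  scaled by daylength), 120 s and 180 s at 1 Hz, linear concentration
  drift `slope = F A Mv / V` with Gaussian noise (default 0.3 ppm), the
  transparent chamber drawn down by uptake and the opaque one driven up
  by respiration.
* **Reflectance**: NDVI saturates exponentially with green LAI,
  `NDVI = ndvi_inf - (ndvi_inf - ndvi_soil) exp(-k_ext greenLAI)`; the
  NIR band is held fixed and the red band solved from NDVI, the 531/570
  pair is near constant (PRI ≈ -0.2), with additive truncated-Gaussian
  band noise. A large `k_ext` (1.4–1.6, dense cereal canopies) makes
  NDVI saturate early in green-up — the mechanism behind the
  winter-crop hysteresis — while potato-like canopies use `k_ext ≈ 0.6`
  and show none.
* **Sampling**: LAI/spectral sampling every 7 days, chamber campaigns
  every 14 — spectral sampling is cheaper in the field and overlaps the
  flux campaigns, and the merged daily table lives on the spectral
  dates because reconstructed `GEP_d` is continuous.

All randomness derives from the config seed (per-day seeds for
closures), so every generated object is bit-reproducible and the
caller's RNG state is left untouched.

## What the generator does *not* emulate

* **Photoinhibition and LUE decline at high PAR.** Synthetic GEP
  responds to PAR through the hyperbola alone, so VI*PAR_d models rank
  *better* on synthetic data than they do in real crops, where midday
  depression and sunny-day sampling weaken the PAR term. Passing tests
  therefore say nothing about VI*PAR_d model skill on real data.
* **Radiative transfer.** Reflectance is a one-parameter saturation
  curve, not a canopy RT model; band noise is additive and independent.
* **Drought and soil moisture.** A dry year is expressed only as a
  lower `lai_max`; there is no process coupling of water stress to
  `alpha` or `gpmax` beyond their LAI dependence.
* **Management events** (fertilization, lodging, harvest timing noise).

# Problem sizes and runtime choices

The test suite runs compact but complete configurations: 70–150 day
seasons with 7–11 campaigns for round-trip and pipeline tests, 50
replicates of a single noisy campaign (8 closure pairs) for the
parameter-recovery study, 1000 replicates of a two-phase equal-slope
simulation for the test-size check, and three pooled seasons of a dense
winter cereal for the hysteresis property. These sizes were chosen so
the whole suite completes in well under a minute while keeping every
statistical check adequately powered.

# Known limitations

* Campaign parameter interpolation is per plot/config; aggregating
  replicate plots per crop before interpolation is left to the caller.
* The respiration-temperature driver choice (soil vs air) can shift
  `rref` by several percent on days with strong soil–air divergence;
  it is configurable and defaults to soil.
* `GEP_d` carries no propagated uncertainty; the campaign fit
  diagnostics (SSE, n) are exposed for callers who want to bootstrap.
* The near-zero QC review is a magnitude rule standing in for the
  visual inspection a field operator would do; its 0.5 umol m-2 s-1
  threshold is configurable.
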