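---
title: "Methods: from lake and catchment measurements to GPP and its landscape drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from lake and catchment measurements to GPP and its landscape drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakescape)
```

## What this package computes

`lakescape` implements the measurement-to-inference chain used to study
gross primary production (GPP) in small northern lakes: how much carbon is
fixed per square metre of lake per day, how that production is partitioned
between the benthic (sediment) and pelagic (water-column) habitats — the
*autotrophic structuring*, expressed as the benthic share of total GPP in
percent — and how both quantities are shaped by the surrounding landscape
(land cover, hydrology, bathymetry) through the lake's water chemistry.

The chain has four stages:

1. **Water-column physics and chemistry.** The light attenuation
   coefficient `Kd` (m^-1) is the absolute OLS slope of `ln(PAR)` against
   depth, fitted to all profile points. Free CO2 is computed from DIC, pH
   and temperature with the freshwater infinite-dilution carbonate
   constants of Plummer & Busenberg (1982); ionic-strength corrections are
   omitted because the target waters are dilute. DIC itself can be
   recovered from headspace equilibration of acidified samples via an
   ideal-gas + Henry's-law mole balance.
2. **Bathymetry.** A depth-area (hypsographic) table is interpolated
   piecewise-linearly; volumes are trapezoid integrals. The littoral
   benthic fraction `%A_littoral` is the share of (planar) sediment area
   shallower than the 1 % light depth `ln(100)/Kd`. Sediment area is
   approximated by planar-area differences without slope correction, the
   standard limnological convention; a flat terminal area at `z_max`
   belongs to the deepest stratum.
3. **Metabolism.** Benthic GPP at discrete depths comes from paired
   light/dark DIC-core incubations (`GPP = R_dark - net_light`, scaled by
   the enclosure volume-to-footprint ratio) or from 24-h transparent dome
   O2 records (`GPP = NEP + R`, with `R` the dark-window O2 decline
   extrapolated to 24 h, converted to carbon with a photosynthetic quotient
   `PQ`, default 1). Pelagic GPP comes from short midday 14C light/dark
   bottle uptakes scaled to daily rates by the incident-PAR ratio. Discrete
   rates are interpolated linearly between measured depths with constant
   extrapolation beyond, then upscaled: benthic rates over sediment area
   per stratum, pelagic rates over water volume, both normalized by the
   lake surface area. Total GPP is the sum; structuring is the benthic
   percentage. Negative rate estimates (possible under noise) are floored
   at zero with a warning; lakes without pelagic data get a
   `missing_pelagic` flag and an undefined total/structuring.
4. **Catchment terrain and inference.** Priority-flood depression filling,
   D8 flow accumulation (ties broken in the fixed order E, SE, S, SW, W,
   NW, N, NE), lake-catchment delineation (the lake is treated as the
   drainage sink, so closed lake basins are never filled away), TWI
   (`ln(a / tan beta)` with a 1e-4 slope floor on flats), land-cover
   reclassification with a 5 % incidental-class exclusion, and the
   hydrology ratios HRT (lake volume over annual discharge, in years) and
   DR (catchment over lake area). The inference layer provides RDA with
   supplementary variables, forward-selection MLR, recursive path analysis
   with ML fit indices, quadratic-peak fits and Pearson correlations.

## Statistical conventions

Path models are recursive (acyclic, uncorrelated errors) and estimated by
per-equation OLS on standardized data, which gives the maximum-likelihood
point estimates for this model class without iteration. The model-implied
covariance keeps exogenous variances/covariances free at their sample
values; the ML discrepancy gives `chi2 = (n - 1) F`, CFI and TLI are
computed against the independence baseline and clamped to [0, 1], and
`RMSEA = sqrt(max(0, chi2 - df) / (df (n - 1)))`. The conventional display
rule keeps only paths with `|coefficient| > 0.3` and `p < 0.05`; the full
model remains available underneath.

RDA standardizes the responses (correlation-matrix scaling, appropriate
for chemistry across mixed units) and reports axis eigenvalues as
percentages of *total* response variance; supplementary variables are
correlated with site scores post hoc and never influence the
eigenstructure. Aliased predictors are dropped with a warning; because the
six land-cover fractions are compositional (they sum to 1), the pipeline
uses "water" as the reference class and constrains on the other five.

Forward selection enters the candidate with the smallest partial-F p-value
while it is below `alpha_enter` (default 0.05, a choice — the convention in
the field is unstated).

Analyses of GPP quantities and the drainage ratio run on log scales;
percentages (littoral fraction, structuring) use a logit with a
[0.5, 99.5] % clamp or a bounded linear scale. `working_scales()` applies
these maps with fixed centring constants so results are comparable across
bundles.

## The synthetic world

`generate_landscape()` draws a self-consistent 26-lake, three-biome
dataset (11 Arctic, 6 subarctic, 9 boreal by default) so every stage of
the pipeline can be tested against known truth without downloads. The
generating model is linear-Gaussian on the fixed working scales, following
the causal ordering land cover -> hydrology -> chemistry -> GPP:

```{r}
true_path_edges()
```

Design choices worth knowing:

* **Signs are fixed by the field's causal understanding** (wetland and
  coniferous cover raise DOC; DOC darkens water; darker water suppresses
  GPP while DOC also fertilizes it; runoff dilutes DOC but raises Kd and
  CO2; wetlands raise TWI and CO2; littoral share raises the benthic
  share; CO2 shifts production pelagic). **Magnitudes were frozen once**
  in a calibration of the stated world so that (i) 26-lake bundles span
  the documented ranges (DOC ~1.5-16 mg/L, Kd ~0.3-4 m^-1, CO2 ~0.1-1.9
  mg/L, pH 5.3-7.8), (ii) total GPP against DOC is unimodal with its
  quadratic-fit vertex in the 8-10 mg/L band, and (iii) the structural
  coefficients are re-identifiable to +-0.1 from a 200-lake bundle. These
  constants are the world definition, not tuning knobs.
* **The DOC-GPP hump is built in explicitly** as a quadratic term in the
  DOC working score that is orthogonalized (by frozen, large-n projection
  coefficients) against every modeled variable. For any linear path model
  over those variables the term behaves as extra residual noise, so fit
  indices stay clean and linear coefficient recovery stays unbiased, while
  the marginal DOC-GPP relation bends into a hump peaking near 9 mg/L.
* **Derived quantities are derived, not drawn.** DIC is back-computed from
  generated CO2, pH and temperature, so carbonate speciation reproduces
  the generated CO2 exactly. The littoral fraction comes from the actual
  basin geometry and Kd (its path-model edges are therefore *emergent* and
  marked `structural = FALSE`; recovery checks skip them). HRT follows the
  exact volume/discharge identity plus ~10 % lognormal reporting noise —
  without that noise HRT would be exactly log-collinear with runoff, DR
  and mean depth and the sample covariance singular.
* **Distributions are truncated lognormal/normal**; the sources only give
  ranges, so the distribution family is a documented choice.
* **Measurement noise is signal-referenced**: concentration series get
  additive noise proportional to the series' dynamic range (instruments
  resolve the change, not 5 % of the absolute DIC), while 14C uptakes and
  PAR readings get multiplicative noise. At zero noise every estimator
  inverts its forward model exactly.
* Two lakes lack pelagic measurements and one boreal lake is a deliberate
  shallow, warm, DOC/CO2-rich high-leverage outlier, both emulating known
  features of real field campaigns; both are switchable off.
* Per-lake rasters are small closed basins whose whole grid drains to the
  central lake, so delineation recovers the intended catchment area; the
  tabulated TWI and runoff are generated at the lake level (like agency
  data) and are not cell-for-cell reproducible from the toy rasters.

What a green test on this world does **not** establish: seasonal dynamics,
stratification, permafrost effects, real sensor drift, spatially
structured land cover, or the exact carbonate constants used by any
particular historical dataset (other standard constant sets differ by a
few percent in CO2).

## Numerical choices and degenerate inputs

* Kd fitting requires >= 3 strictly positive PAR readings and errors on
  non-decreasing light; profiles with sub-surface maxima are fitted as-is
  with the r-squared reported.
* Upscaling uses 1000 integration strata by default; results change by
  less than 1e-3 (relative) between 100 and 10 000 strata for smooth
  profiles.
* D8 ties are broken deterministically; interior flats drain along the
  priority-flood pop order; boundary cells with no downhill neighbour are
  outlets.
* The dome estimator clamps a negative respiration (O2 rising in the
  dark) to zero with a warning rather than propagating a physically
  impossible value.
* `fit_path_model()` errors on cyclic graphs, singular parent sets and
  missing values; a saturated model reproduces the sample covariance
  exactly (chi2 = 0, CFI = 1, RMSEA = 0).

## Known limitations

* Recovery of weakly identified cover-driven edges (e.g. wetland -> TWI)
  at n = 200 has standard errors around 0.05-0.08; occasional seeds
  exceed the +-0.1 band even though the estimator is unbiased. The
  acceptance checks use the fixed seeds named in the test suite.
* A field-campaign-sized analysis (n = 26) identifies structural
  coefficients only to roughly +-0.3 — one reason path models at that
  scale should be read as conceptual frameworks; the synthetic world
  reproduces that behaviour.
* Manual DEM corrections (breaching against orthophotos, infrastructure
  masking) used in real workflows are replaced by automatic filling.
* HRT is printed in years (volume over annual discharge); sources that
  label the same ratio "year^-1" are assumed to mean years.
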