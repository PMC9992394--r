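---
title: "Harmonizing soil-test phosphorus and mapping Olsen-P stocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing soil-test phosphorus and mapping Olsen-P stocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olsenp)
```

## The problem

Plant-available soil phosphorus is measured with half a dozen incompatible
extraction tests — Olsen (bicarbonate), Bray-I and Kirsanov (acid), Mehlich-3,
anion-exchange resin, AB-DPTA — at assorted depths, units and detection
limits. Any attempt to map plant-available P across regions or continents
must first funnel this heterogeneity into a single quantity. `olsenp`
implements that funnel end to end, with Olsen P in the 0–20 cm topsoil layer
(mg P kg⁻¹ soil) as the common currency, and then carries the harmonized
concentrations through a predictive model to areal phosphorus *stocks*
(kilotonnes per region).

The pipeline has five stages, each a package module:

1. **Screening** (`filter_samples()`): keep comparable assay chemistry
   (molybdenum-blue colorimetry, ion chromatography), mass-based units, and
   records that are correctly georeferenced on land within an acceptable
   sampling window; substitute left-censored values by half the detection
   limit.
2. **Conversion** (`convert_samples()`): map Bray-I, Mehlich-3, Resin,
   Kirsanov and AB-DPTA values to Olsen P by published linear regressions,
   combined as sample-size-weighted means, with calcareous/non-calcareous
   routing and a pH ≥ 7 rejection gate for acid extractants.
3. **Depth standardization** (`harmonize_samples()`): average multi-depth
   profiles to 0–20 cm in proportion to each layer's overlap with that
   interval (times bulk density when known) and collapse duplicates.
4. **Modelling** (`fit_olsen_model()`): a generalized additive model of log
   Olsen P on environmental covariates, with PCA reduction of collinear
   covariate families, a 5 % "other"-country device, and smearing correction
   of the retransformation bias.
5. **Stocks** (`stock_grid()`, `aggregate_stocks()`): per-pixel mass
   `conc × bulk density × depth × area`, lognormal coefficients of
   variation, biome-based overrides in data-poor biomes, and additive
   regional aggregation.

## Screening rules and their rationale

The stannous-chloride colorimetric assay reads systematically differently
from molybdenum blue and is excluded outright; volumetric results
(mg L⁻¹) cannot be converted to a mass basis without the sample's density
and are likewise dropped. Unreported detection limits are inferred from a
source's *repeated low values*: a value that recurs at least 10 times, sits
in the source's lowest decile and lies strictly below its median is taken to
be an already-substituted half-limit, so the implied limit is twice it. The
decile-plus-below-median condition is what keeps a constant-valued source
from declaring its only value a detection limit. Values strictly below the
limit (or flagged) become half the limit; values printed exactly *at* the
limit are left untouched by default (`at_limit_censored` flips this),
because silently altering a valid measurement is the worse failure mode.

The temporal window defaults to 2000–2019. Sources representing long-stable
land uses may be exempted via `exempt_sources`; the configured Chinese
national survey source additionally drops its intensified eastern provinces
and anything sampled before 1995. Coordinates exactly (0, 0) are treated as
a missing-georeference placeholder (configurable), and an optional land mask
removes points in water, glaciers or permanent snowpack.

## The conversion registry

Component regressions are combined per test and soil class by weighting
slope, intercept and R² with each study's sample size. Sample sizes printed
as approximate ("~180", "~60") are taken at face value. The shipped
`default_registry()` carries the published rounded combined coefficients —
e.g. Olsen = 0.49 × Bray-I + 3.1, Olsen = 0.47 × Mehlich-3 + 2.4
(non-calcareous) and 0.41 × Mehlich-3 + 1.1 (calcareous) — because those
rounded forms are the conversion tool as it circulates and validates;
`default_registry(printed = FALSE)` recombines the component rows at full
precision (slopes 0.4772, 0.4121, 0.4975), which agrees with the rounded
forms to one unit in the last printed digit.

Two routing decisions deserve a note. Kirsanov (0.2 N HCl) has no published
Olsen conversion of its own; the combined Bray-I equation is its closest
extractant analogue, and we apply the Bray-I pH ≥ 7 gate to it as well, for
consistency — acid extractants on calcareous soils dissolve calcium
phosphates that plants cannot use, inflating the reading. The single
calcareous Resin coefficient (0.94) is implemented as a slope with zero
intercept. Records of unknown soil class are routed by pH
(`classify_calcareous()`, calcareous at pH ≥ 7.5). Converted values are
floored at zero; with the combined equations (all non-negative intercepts)
the floor is a safety net only.

## Depth standardization

A layer's weight in the 0–20 cm mean is the fraction of that interval it
covers — a 15–25 cm sample counts a quarter — multiplied by its bulk density
when available. Weights are renormalized over the contributing layers, so a
profile sampled only at 0–10 cm still yields a value and is taken as
representative of the full interval; no downward extrapolation for
stratification is attempted (phosphorus stratifies weakly below the plough
layer because topsoil sorbs it strongly). A strict mode (`min_coverage`)
drops poorly covering profiles instead. Sites sampled only below 20 cm are
dropped.

Duplicates collapse in two stages: exact repeats (same rounded coordinates,
date and value) are removed first; remaining multiple values at the same
coordinates are averaged. Coordinates match after rounding to 5 decimal
places (≈ 1 m). Quartiles in `outlier_summary()` use linear interpolation
between order statistics (R's default type 7); the convention is fixed here
for reproducibility since fences move with it. Outliers are reported, never
removed.

## The model and the smearing correction

Concentrations are modelled on the natural-log scale, where their
distribution is approximately normal (the Shapiro–Wilk W is reported, and
the fit warns rather than stops when it is low — at large n the test rejects
trivially small departures). Continuous covariates enter as penalized
smooths via `mgcv::gam`; families of collinear monthly covariates should be
collapsed first with `pca_reduce()`, which keeps the minimal leading set of
components reaching a cumulative-variance target (default 0.95 — a
threshold, not a fixed count, so the retained dimension adapts to the data).
Categorical covariates (country, biome, development status, soil group)
enter as factors. `other_country_augment()` relabels a seeded 5 % of each
country's rows as `"other"` before fitting — in place by default, which is
the literal reading of "renamed"; appending copies is available as an
option — so predictions for countries absent from training fall back on a
data-weighted average country effect.

Back-transformed predictions `exp(ŷ)` estimate the conditional median and
systematically undershoot the mean. The smearing estimator
`S = mean(exp(residuals))` corrects this without a distributional
assumption; it is applied globally, which presumes homoscedastic residuals.
`S ≥ 1` for mean-zero residuals (Jensen), and the package asserts this on
every fit. Model quality is reported as AIC (from the GAM, log scale) plus
R² and NSE computed on the concentration scale between observations and
smearing-corrected predictions — stocks live on the concentration scale, so
that is where predictive skill matters; the scale choice is stated here
because both conventions exist.

## Stocks, uncertainty and overrides

A pixel's stock in kilotonnes is
`concentration·10⁻⁶ × bulk density × 0.2 m × area / 10⁶`, with spherical
cell areas from `cell_area_m2()`. Per-pixel uncertainty uses the lognormal
CV `sqrt(exp(s²) − 1)` of the log-scale prediction SD. Regional uncertainty
is reported as the region's mean pixel CV times its total — a documented
reporting convention, not a formal propagation (pixel errors are neither
independent nor summed in quadrature here).

Five unproductive biomes are too data-poor to model and receive literature
constants instead: deserts 2.0, flooded grasslands/savannas and mangroves
(developed) 5.4, tropical/subtropical dry broadleaf forests 3.5, montane
grasslands/shrublands (underdeveloped) 3.1 mg kg⁻¹, and a terrain rule
mapping pixels linearly from 3 (gentle, low) down to 1 (steep, high)
mg kg⁻¹ over configurable slope/elevation bounds — the linear form is this
package's choice, since only the 1–3 range is published. Overrides are
idempotent and entirely data-driven through the rule table.

`mehlich_stock_to_olsen()` supports cross-study comparison of stock maps
published on a Mehlich-3 basis: it converts *concentrations* per pixel and
recomputes stocks, because the conversion intercept makes converting stock
totals directly inequivalent.

## What the synthetic generator emulates — and what it does not

`generate_samples()`/`generate_rasters()` build a small world — four
countries on two continents over a 40 × 40 grid of 0.025° cells with a
water block, a southern desert band, smooth covariate surfaces and a pH
field — and draw sites whose log concentrations follow a known additive
surface (`β₀ + tanh(cov1) + 0.6 sin(2 cov2) + country offset`) with
multiplicative lognormal noise. Defaults are chosen once to mirror realistic
study conditions: σ = 0.6 on the log scale (a model explaining roughly half
the log-scale variance), β₀ = ln 20 so mean concentrations land near
26–30 mg kg⁻¹, a method mix of 57 % Olsen / 37.4 % Bray-I / 4.7 % Mehlich-3
with traces of Resin, Kirsanov and AB-DPTA, a 2 mg kg⁻¹ detection limit with
≈ 0.1 % censoring, 15 % two-layer profiles, small duplicate fractions and
planted contaminant records in deterministic counts, 2 000 sites in total.

Non-Olsen tests are generated by *inverting* the combined conversion
equations, so conversion is exactly recoverable; sites whose inversion would
fall below the detection limit keep the Olsen method (a laboratory would not
report such a value). Every record's expected fate — kept, or discarded with
a specific reason — is written to a ground-truth manifest, which the test
suite compares against the pipeline's audit trail record by record.

What the generator does **not** emulate: spatial autocorrelation structures
of real climate fields, method-specific measurement error beyond the single
lognormal term, heteroscedasticity, reporting-precision artefacts, or the
geopolitical irregularity of real country borders. Passing the recovery
tests therefore demonstrates that the pipeline's *mathematics* is faithful —
filters count what they claim, conversions invert, depth weights average,
the smearing correction removes the retransformation bias — not that the
fitted model would attain any particular skill on real soils.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: empty equation lists, constant
PCA columns, zero-variance observations and empty residual vectors are
errors; all-zero depth overlap drops the site with a recorded reason;
missing slope/elevation under a terrain override falls back to the range
midpoint with a warning; zero observed values in residual classification go
to the worst class with a warning. Ties in quartiles follow type-7
interpolation. The test suite and the acceptance script run the full
pipeline at 2 000 sites on a 40 × 40 grid and the smearing-correction
comparison over 100 replicates of 300 sites — sizes at which every
stochastic check is stable across seeds while the whole suite completes in
well under a minute on a single core.

## Known limitations

- Grids are plain lon/lat matrices (`p_grid`) with CSV serialization;
  GeoTIFF I/O and projected coordinate systems are out of scope.
- Region polygons are handled by an even-odd ray-casting containment test on
  GeoJSON rings; degenerate or self-intersecting polygons are not repaired.
- The regional uncertainty convention (mean CV × total) understates or
  overstates formally propagated error depending on the spatial error
  correlation.
- The conversion registry applies published coefficients; it does not refit
  the underlying regressions from raw soils data.
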