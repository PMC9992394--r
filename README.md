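# olsenp

Harmonization of heterogeneous soil-test phosphorus data into Olsen-P
concentrations, and mapping of the result into areal phosphorus stocks.

## The problem

Plant-available soil phosphorus is reported with incompatible extraction
tests (Olsen, Bray-I, Mehlich-3, anion-exchange resin, Kirsanov, AB-DPTA),
at assorted depths, units and detection limits. Agronomists and
biogeochemists who want a consistent picture of available P — where
fertiliser is needed, where soil P can be drawn down — must first harmonize
these sources. `olsenp` implements that harmonization as a tested pipeline
for R, with bicarbonate-extractable **Olsen P in the 0–20 cm topsoil**
(mg P kg⁻¹) as the common currency:

1. **Screen** raw multi-source tables for comparable assay chemistry and
   units, georeferencing, land mask and sampling window, with an audited
   report of every discard, and substitute left-censored values by half the
   detection limit.
2. **Convert** other soil tests to Olsen P with sample-size-weighted linear
   equations, `olsen = a·x + b`, routed by calcareous soil class and gated
   at pH ≥ 7 for acid extractants (e.g. Olsen = 0.49 × Bray-I + 3.1;
   0.47 × Mehlich-3 + 2.4 non-calcareous, 0.41 × Mehlich-3 + 1.1
   calcareous).
3. **Standardize depth** by averaging profile layers in proportion to their
   overlap with 0–20 cm (× bulk density), and collapse duplicates.
4. **Model** log Olsen P with a generalized additive model (mgcv),
   principal-component reduction of collinear covariates, an
   "other"-country device for unseen countries, and the smearing
   retransformation correction `S = mean(exp(residuals))` so that
   back-transformed predictions `S·exp(ŷ)` estimate the conditional mean.
5. **Compute stocks**: per-pixel mass
   `conc·10⁻⁶ × bulk density × 0.2 m × area` in kilotonnes, lognormal
   coefficients of variation `sqrt(exp(s²) − 1)`, literature overrides in
   five data-poor biomes, and additive aggregation to country, continent
   and globe.

A seeded synthetic-data module (`generate_samples()`, `generate_rasters()`)
builds a miniature world with a known ground truth — including planted
contaminant records with predetermined pipeline fates — so the entire chain
is testable without downloading anything.

## Worked example

```r
library(olsenp)

cfg   <- synth_config(seed = 42L)            # 2000 sites, 4 countries
world <- generate_rasters(cfg)
raw   <- generate_samples(cfg)$samples       # 2420 raw records

filt <- filter_samples(raw, filter_config(land_mask = world$land_mask))
str(filt$report)
#> List of 4
#>  $ input_n            : int 2420
#>  $ kept_n             : int 2360
#>  $ discarded_n        : int 60
#>  $ discarded_by_reason:List of 4
#>   ..$ land_mask: int 10
#>   ..$ method   : int 20
#>   ..$ unit     : int 10
#>   ..$ year     : int 20

kept <- filt$records[filt$records$filter_status == "kept", ]
conv <- convert_samples(kept)                # 1002 converted, 1358 Olsen
harm <- harmonize_samples(conv)              # 2000 sites at 0-20 cm

tab <- extract_predictors(harm$samples,
                          list(cov1 = world$covariates$cov1,
                               cov2 = world$covariates$cov2))$table
fit <- fit_olsen_model(tab, smooth_vars = c("cov1", "cov2"),
                       factor_vars = "country",
                       response = "olsen_p_0_20", seed = 1)
fit
#> <olsen_fit> log-scale additive model
#>   smooth terms : cov1, cov2
#>   factor terms : country
#>   training rows: 2000   residual SD (log): 0.628
#>   smearing S   : 1.2108   Shapiro-Wilk W: 0.998
#>   R2: 49.0%   NSE: 0.490   AIC: 3847.2

sg <- biome_override(stock_grid_from_rasters(world, s_ln = fit$resid_sd))
aggregate_stocks(sg, "continent")
#>     region  area_km2 stock_kt   mean_cv uncertainty_kt n_pixels
#> 1   austra  6181.856 23.87048 0.6948679       16.58683      800
#> 2 borealia  5687.344 34.29934 0.6948679       23.83352      736
#> 3   global 11869.200 58.16982 0.6948679       40.42035     1536
```

Reading the output: the filter report accounts for every input record
(2420 = 2360 kept + 60 discarded, with the planted contaminant counts
recovered exactly). The fitted residual SD on the log scale (0.628) sits
within 5 % of the generating noise (σ = 0.6), and the smearing factor
1.21 ≈ exp(σ²/2) is the multiplicative correction the naive back-transform
would have missed — about a 20 % underestimate of mean concentrations. The
stock table is additive by construction: continental totals sum exactly to
the global 58.17 kt of this miniature world.

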