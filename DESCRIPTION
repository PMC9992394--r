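Package: olsenp
Title: Harmonization and Stock Mapping of Plant-Available Soil Phosphorus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to harmonize heterogeneous soil-test phosphorus
    measurements (Bray-I, Mehlich-3, Resin, Kirsanov, AB-DPTA) into Olsen
    phosphorus concentrations for the 0-20 cm topsoil layer, and to map the
    harmonized data into areal phosphorus stocks. Provides method, unit,
    detection-limit and space-time screening with an audit trail,
    sample-size-weighted linear conversion equations with calcareous-soil and
    pH routing, depth-weighted profile standardization and deduplication,
    log-scale additive modelling of concentrations from environmental
    covariates with principal-component reduction and smearing
    retransformation-bias correction, biome-based overrides, per-pixel stock
    and lognormal coefficient-of-variation calculation with regional
    aggregation, and a seeded synthetic-data generator with a ground-truth
    manifest for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
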