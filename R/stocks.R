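#' Per-pixel stock table
#'
#' Canonical tabular form of a stock grid: one row per land pixel with the
#' predicted concentration, bulk density, depth, cell area, region labels and
#' log-scale prediction SD. [pixel_stock()] and [lognormal_cv()] fill the
#' `stock_kt` and `cv` columns.
#'
#' @param concentration mg P kg^-1 per pixel.
#' @param bulk_density kg m^-3 per pixel (recycled).
#' @param area_m2 pixel area, m^2 (recycled).
#' @param depth_m topsoil depth, m (default 0.2 = 20 cm).
#' @param country,continent,biome,development optional label vectors
#'   (recycled); default `"unassigned"` / `NA`.
#' @param s_ln optional per-pixel log-scale SD for the CV (recycled).
#' @param lon,lat optional pixel-center coordinates.
#' @return data.frame of class `stock_grid` with `stock_kt` and `cv`
#'   computed.
#' @export
stock_grid <- function(concentration, bulk_density, area_m2, depth_m = 0.2,
                       country = "unassigned", continent = "unassigned",
                       biome = NA_character_, development = NA_character_,
                       s_ln = NA_real_, lon = NA_real_, lat = NA_real_) {
  n <- length(concentration)
  df <- data.frame(
    lon = rep_len(lon, n), lat = rep_len(lat, n),
    concentration = concentration,
    bulk_density = rep_len(bulk_density, n),
    depth_m = rep_len(depth_m, n),
    area_m2 = rep_len(area_m2, n),
    country = rep_len(country, n), continent = rep_len(continent, n),
    biome = rep_len(biome, n), development = rep_len(development, n),
    s_ln = rep_len(s_ln, n), stringsAsFactors = FALSE)
  df$stock_kt <- pixel_stock(df$concentration, df$bulk_density, df$depth_m,
                             df$area_m2)
  df$cv <- ifelse(is.na(df$s_ln), NA_real_, lognormal_cv(
    ifelse(is.na(df$s_ln), 0, df$s_ln)))
  class(df) <- c("stock_grid", "data.frame")
  df
}

#' Phosphorus mass of one pixel, in kilotons
#'
#' `stock = concentration * 1e-6 [kg P / kg soil] * bulk_density [kg m^-3]
#' * depth [m] * area [m^2]`, converted to kilotons (1 kt = 1e6 kg).
#' Multilinear in all four arguments.
#'
#' @param concentration mg P kg^-1 soil.
#' @param bulk_density kg m^-3.
#' @param depth_m topsoil depth, m.
#' @param area_m2 pixel area, m^2.
#' @return stock in kt (vectorized).
#' @export
pixel_stock <- function(concentration, bulk_density, depth_m, area_m2) {
  stopifnot(all(concentration >= 0, na.rm = TRUE),
            all(bulk_density >= 0, na.rm = TRUE),
            all(depth_m >= 0), all(area_m2 >= 0))
  concentration * 1e-6 * bulk_density * depth_m * area_m2 / 1e6
}

#' Coefficient of variation of a lognormal estimate
#'
#' For a lognormal variable with log-scale SD `s_ln`, the coefficient of
#' variation is `sqrt(exp(s_ln^2) - 1)`: 0 at `s_ln = 0`, asymptotically
#' equal to `s_ln` for small values, and strictly increasing.
#'
#' @param s_ln log-scale standard deviation (>= 0, vectorized).
#' @return cv (unitless).
#' @export
lognormal_cv <- function(s_ln) {
  if (any(s_ln < 0, na.rm = TRUE)) stop("s_ln must be non-negative")
  sqrt(exp(s_ln^2) - 1)
}

#' Biome override rules for data-poor biomes
#'
#' Literature replacement concentrations for the unproductive biomes with too
#' few samples to model: deserts 2.0; flooded grasslands/savannas and
#' mangroves in developed countries 5.4; tropical/subtropical dry broadleaf
#' forests 3.5; montane grasslands/shrublands in underdeveloped countries
#' 3.1; and a slope/elevation-dependent range rule mapping to 1-3 mg kg^-1
#' (gentle low terrain -> 3, steep high terrain -> 1).
#'
#' @return data.frame with columns `biome`, `development` (`NA` = any),
#'   `type` (`"constant"`/`"range"`), `lo`, `hi`.
#' @export
default_biome_rules <- function() {
  data.frame(
    biome = c("desert",
              "flooded_grasslands_savannas_mangroves",
              "tropical_subtropical_dry_broadleaf_forest",
              "montane_grasslands_shrublands",
              "rock_and_ice_sparse"),
    development = c(NA, "developed", NA, "underdeveloped", NA),
    type = c("constant", "constant", "constant", "constant", "range"),
    lo = c(2.0, 5.4, 3.5, 3.1, 1.0),
    hi = c(2.0, 5.4, 3.5, 3.1, 3.0),
    stringsAsFactors = FALSE)
}

#' Replace modelled concentrations in data-poor biomes
#'
#' Applies [default_biome_rules()]-style overrides to a [stock_grid()] table:
#' constant rules set the concentration outright; range rules map pixels
#' linearly from `hi` (minimum slope and elevation) down to `lo` (maximum),
#' using slope/elevation normalized over `slope_range` / `elev_range`.
#' Pixels of a range-rule biome with missing slope or elevation fall back to
#' the range midpoint with a warning. Idempotent, and recomputes `stock_kt`.
#'
#' @param grid a `stock_grid`.
#' @param rules override rule table (default [default_biome_rules()]).
#' @param slope,elevation per-pixel slope (%) and elevation (m) vectors
#'   (needed only when a range rule applies).
#' @param slope_range,elev_range normalization bounds for the range rule.
#' @return the grid with overridden concentrations and updated stocks.
#' @export
biome_override <- function(grid, rules = default_biome_rules(),
                           slope = NULL, elevation = NULL,
                           slope_range = c(0, 60),
                           elev_range = c(0, 5000)) {
  stopifnot(all(rules$lo <= rules$hi), all(rules$lo > 0))
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    hit <- !is.na(grid$biome) & grid$biome == r$biome
    if (!is.na(r$development))
      hit <- hit & !is.na(grid$development) & grid$development == r$development
    if (!any(hit)) next
    if (r$type == "constant") {
      grid$concentration[hit] <- r$lo
    } else {
      sl <- if (is.null(slope)) rep(NA_real_, nrow(grid)) else slope
      el <- if (is.null(elevation)) rep(NA_real_, nrow(grid)) else elevation
      norm01 <- function(x, rng)
        pmin(1, pmax(0, (x - rng[1]) / (rng[2] - rng[1])))
      sev <- (norm01(sl, slope_range) + norm01(el, elev_range)) / 2
      val <- r$hi - (r$hi - r$lo) * sev
      missing_terrain <- hit & (is.na(sl) | is.na(el))
      if (any(missing_terrain)) {
        warning(sum(missing_terrain),
                " pixel(s) missing slope/elevation; using range midpoint")
        val[missing_terrain] <- (r$lo + r$hi) / 2
      }
      grid$concentration[hit] <- val[hit]
    }
  }
  grid$stock_kt <- pixel_stock(grid$concentration, grid$bulk_density,
                               grid$depth_m, grid$area_m2)
  grid
}

#' Aggregate pixel stocks to regional totals
#'
#' Sums pixel stocks and areas by region label (country or continent) and
#' appends a global row. Reported uncertainty is the region's mean pixel CV
#' times its total stock — a reporting convention, not a formal error
#' propagation. Pixels with a missing label fall into an `"unassigned"`
#' bucket rather than being dropped, so totals always conserve mass.
#'
#' @param grid a `stock_grid`.
#' @param by label column to aggregate over (default `"country"`).
#' @return data.frame with `region`, `area_km2`, `stock_kt`, `mean_cv`,
#'   `uncertainty_kt`, `n_pixels`; last row `"global"`.
#' @export
aggregate_stocks <- function(grid, by = "country") {
  stopifnot(by %in% names(grid))
  lab <- grid[[by]]
  lab[is.na(lab)] <- "unassigned"
  regions <- sort(unique(lab))
  rows <- lapply(regions, function(rg) {
    sel <- lab == rg
    mcv <- if (all(is.na(grid$cv[sel]))) NA_real_ else
      mean(grid$cv[sel], na.rm = TRUE)
    tot <- sum(grid$stock_kt[sel])
    data.frame(region = rg,
               area_km2 = sum(grid$area_m2[sel]) / 1e6,
               stock_kt = tot, mean_cv = mcv,
               uncertainty_kt = if (is.na(mcv)) NA_real_ else mcv * tot,
               n_pixels = sum(sel), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  gcv <- if (all(is.na(grid$cv))) NA_real_ else mean(grid$cv, na.rm = TRUE)
  gtot <- sum(grid$stock_kt)
  rbind(out, data.frame(
    region = "global", area_km2 = sum(grid$area_m2) / 1e6,
    stock_kt = gtot, mean_cv = gcv,
    uncertainty_kt = if (is.na(gcv)) NA_real_ else gcv * gtot,
    n_pixels = nrow(grid), stringsAsFactors = FALSE))
}

#' Classify prediction residuals into percentage-difference bands
#'
#' Per-point percentage difference `100 * |predicted - observed| / observed`,
#' binned into the bands 0-2, 2.1-5, 5.1-10, 10.1-25 and >25 % (boundaries
#' closed on the right: `[0,2], (2,5], (5,10], (10,25], (25,Inf)`). Points
#' with a zero observed value have an undefined relative difference and are
#' classed `>25` with a warning.
#'
#' @param observed,predicted equal-length non-negative vectors.
#' @return list with `counts` and `shares` (named, shares sum to 100) and
#'   the per-point `pct_diff` and `class` vectors.
#' @export
residual_classes <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted),
            all(observed >= 0), all(predicted >= 0))
  labels <- c("0-2", "2.1-5", "5.1-10", "10.1-25", ">25")
  pct <- ifelse(observed == 0, Inf,
                100 * abs(predicted - observed) / observed)
  if (any(observed == 0))
    warning(sum(observed == 0),
            " point(s) with observed = 0 classed as >25%")
  cls <- cut(pct, breaks = c(-Inf, 2, 5, 10, 25, Inf), labels = labels)
  counts <- table(cls)
  list(counts = stats::setNames(as.integer(counts), labels),
       shares = stats::setNames(100 * as.integer(counts) / length(pct),
                                labels),
       pct_diff = pct, class = as.character(cls))
}

#' Convert a Mehlich-3 stock grid to Olsen-equivalent stocks
#'
#' Cross-study comparison helper: recovers the per-pixel Mehlich-3
#' concentration, converts it with the class-appropriate combined equation
#' (calcareous vs non-calcareous; all pixels treated non-calcareous, with a
#' warning, when no mask is given), and recomputes the stock. The conversion
#' acts on concentrations, not stock totals, because the linear intercept
#' makes the two routes inequivalent.
#'
#' @param grid a `stock_grid` whose `concentration` column is Mehlich-3 P.
#' @param calcareous logical per-pixel mask (`TRUE` = calcareous), or `NULL`.
#' @param registry a `conversion_registry`.
#' @return the grid with Olsen concentrations and recomputed `stock_kt`.
#' @export
mehlich_stock_to_olsen <- function(grid, calcareous = NULL,
                                   registry = default_registry()) {
  if (is.null(calcareous)) {
    warning("no calcareous mask supplied; treating all pixels as non-calcareous")
    calcareous <- rep(FALSE, nrow(grid))
  }
  eq_nc <- registry$combined[registry$combined$method == "mehlich3" &
                             registry$combined$soil_class == "non_calcareous", ]
  eq_c <- registry$combined[registry$combined$method == "mehlich3" &
                            registry$combined$soil_class == "calcareous", ]
  conc <- grid$concentration
  grid$concentration <- ifelse(
    calcareous,
    as.numeric(to_olsen(conc, eq_c)),
    as.numeric(to_olsen(conc, eq_nc)))
  grid$stock_kt <- pixel_stock(grid$concentration, grid$bulk_density,
                               grid$depth_m, grid$area_m2)
  grid
}
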