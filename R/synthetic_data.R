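#' Configuration for the synthetic soil-sample generator
#'
#' Declares the study conditions the generator emulates: a small gridded
#' world of four countries on two continents, smooth covariate fields, a
#' known additive log-concentration surface with lognormal noise, a realistic
#' soil-test method mix, detection-limit censoring, multi-depth profiles,
#' duplicates, and planted contaminant records with known pipeline fates.
#'
#' @param n_sites named integer vector of sites per country (names are the
#'   country labels; countries are laid out as longitude strips).
#' @param grid_nx,grid_ny grid dimensions (default 40 x 40 cells).
#' @param res cell size, degrees (default 0.025).
#' @param xmin,ymin lower-left corner of the grid (degrees).
#' @param sigma log-scale SD of the multiplicative lognormal noise.
#' @param beta0 baseline log concentration (default `log(20)`).
#' @param country_offsets additive log-scale country effects (recycled over
#'   countries).
#' @param method_mix named fractions per soil test, summing to 1.
#' @param detection_limit censoring limit, mg kg^-1.
#' @param below_limit_frac fraction of records censored below the limit.
#' @param multi_depth_frac fraction of sites sampled as a two-layer profile
#'   (0-15 and 15-25 cm) instead of a single 0-20 cm sample.
#' @param dup_exact_frac fraction of sites duplicated as an exact copy.
#' @param dup_coord_frac fraction of sites given a second, different value at
#'   identical coordinates (merged by mean downstream).
#' @param contam_stannous,contam_volumetric,contam_off_window,contam_off_land
#'   fractions of planted contaminant records (relative to the site count)
#'   expected to be discarded with reasons method/unit/year/land_mask.
#' @param year_window sampling-year window used for valid records.
#' @param bulk_density constant bulk density, kg m^-3.
#' @param seed integer seed driving every random draw.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_sites = c(aland = 500L, borland = 500L,
                                     cordia = 500L, dorsia = 500L),
                         grid_nx = 40L, grid_ny = 40L, res = 0.025,
                         xmin = 0, ymin = 0,
                         sigma = 0.6, beta0 = log(20),
                         country_offsets = c(0, 0.3, -0.2, 0.15),
                         method_mix = c(olsen = 0.569, bray1 = 0.374,
                                        mehlich3 = 0.047, resin = 0.005,
                                        kirsanov = 0.004, abdpta = 0.001),
                         detection_limit = 2, below_limit_frac = 0.001,
                         multi_depth_frac = 0.15,
                         dup_exact_frac = 0.02, dup_coord_frac = 0.01,
                         contam_stannous = 0.01, contam_volumetric = 0.005,
                         contam_off_window = 0.01, contam_off_land = 0.005,
                         year_window = c(2000L, 2019L),
                         bulk_density = 1300, seed = 1L) {
  stopifnot(sigma >= 0, abs(sum(method_mix) - 1) < 1e-8,
            all(method_mix >= 0),
            !is.null(names(n_sites)), all(n_sites >= 0))
  fr <- c(below_limit_frac, multi_depth_frac, dup_exact_frac,
          dup_coord_frac, contam_stannous, contam_volumetric,
          contam_off_window, contam_off_land)
  stopifnot(all(fr >= 0 & fr <= 1))
  structure(as.list(environment()), class = "synth_config")
}

# Deterministic smooth field: sum of seeded Gaussian bumps, standardized.
.bump_field <- function(nx, ny, res, xmin, ymin, n_bumps = 6L) {
  cx <- xmin + (seq_len(nx) - 0.5) * res
  cy <- ymin + (seq_len(ny) - 0.5) * res
  f <- matrix(0, ny, nx)
  ext <- max(nx, ny) * res
  for (b in seq_len(n_bumps)) {
    x0 <- stats::runif(1, xmin, xmin + nx * res)
    y0 <- stats::runif(1, ymin, ymin + ny * res)
    amp <- stats::runif(1, -2, 2)
    w <- stats::runif(1, 0.15, 0.40) * ext
    f <- f + amp * outer(cy, cx, function(y, x)
      exp(-((x - x0)^2 + (y - y0)^2) / (2 * w^2)))
  }
  (f - mean(f)) / stats::sd(f)
}

# Shared world-building: covariate/pH/label fields for a config. Sets the
# RNG from config$seed, so samples and rasters built from the same config see
# the same world.
.synth_fields <- function(config) {
  set.seed(config$seed)
  nx <- config$grid_nx; ny <- config$grid_ny
  res <- config$res; xmin <- config$xmin; ymin <- config$ymin
  cov1 <- .bump_field(nx, ny, res, xmin, ymin)
  cov2 <- .bump_field(nx, ny, res, xmin, ymin)
  cov3 <- .bump_field(nx, ny, res, xmin, ymin)
  ph <- 5.5 + 2.8 * stats::pnorm(cov3)

  countries <- names(config$n_sites)
  ncty <- length(countries)
  col_country <- pmin(ncty, ceiling(seq_len(nx) / (nx / ncty)))
  country_idx <- matrix(rep(col_country, each = ny), ny, nx)
  # water block: north-east corner (no land, no country)
  water <- matrix(FALSE, ny, nx)
  wb <- max(1L, 8L)
  water[(ny - wb + 1L):ny, (nx - wb + 1L):nx] <- TRUE
  land <- ifelse(water, 0, 1)
  country_idx[water] <- NA_integer_

  offs <- rep_len(config$country_offsets, ncty)
  mu <- config$beta0 + 1.0 * tanh(cov1) + 0.6 * sin(2 * cov2)
  for (i in seq_len(ncty)) mu[which(country_idx == i)] <-
    mu[which(country_idx == i)] + offs[i]

  biome_idx <- matrix(2L, ny, nx)  # temperate by default
  biome_idx[1:max(1L, floor(ny / 5)), ] <- 1L  # southern desert band
  biome_labels <- c(`1` = "desert", `2` = "temperate_broadleaf_mixed_forest")

  half <- ceiling(ncty / 2)
  continent_of_country <- c(rep("austra", half), rep("borealia", ncty - half))
  development_of_country <- rep(c("developed", "underdeveloped"),
                                length.out = ncty)
  names(continent_of_country) <- countries
  names(development_of_country) <- countries

  slope <- matrix(pmin(60, pmax(0, 15 + 12 * cov3)), ny, nx)     # percent
  elev <- matrix(pmin(5000, pmax(0, 800 + 500 * cov1)), ny, nx)  # m

  list(cov1 = cov1, cov2 = cov2, cov3 = cov3, ph = ph, mu = mu,
       land = land, water = water, country_idx = country_idx,
       countries = countries, offsets = offs,
       biome_idx = biome_idx, biome_labels = biome_labels,
       continent_of_country = continent_of_country,
       development_of_country = development_of_country,
       slope = slope, elev = elev,
       nx = nx, ny = ny, res = res, xmin = xmin, ymin = ymin)
}

# Deterministic per-category counts from fractions: largest-remainder rounding
# so counts sum to round(sum(frac)*n).
.alloc_counts <- function(n, frac) {
  raw <- frac * n
  base <- floor(raw)
  left <- round(sum(raw)) - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1L
  }
  stats::setNames(as.integer(base), names(frac))
}

#' Generate a multi-source soil-sample table with a ground-truth manifest
#'
#' Simulates the raw inputs the harmonization pipeline consumes. Each site
#' gets a true log concentration from the known additive surface plus a
#' lognormal noise draw; non-Olsen soil tests are generated by *inverting*
#' the registry's combined conversion equations (`raw = (olsen - intercept) /
#' slope`), so conversion must recover the site's Olsen value exactly.
#' Bray-I/Kirsanov tests are only assigned to sites with pH < 7 (where the
#' test is valid); a site whose inversion would go negative keeps the Olsen
#' method. Censoring, two-layer depth profiles, exact and coordinate
#' duplicates, and contaminant records (stannous-chloride assay, volumetric
#' unit, off-window year, off-land coordinates) are planted in deterministic
#' counts with seeded placement, and every record's expected pipeline fate is
#' written to the manifest.
#'
#' @param config a [synth_config()].
#' @param registry conversion registry used for the inverse mapping (default
#'   [default_registry()]; use the same registry in the pipeline under test).
#' @return list with `samples` (canonical raw table), `manifest` (list:
#'   `truth` per-site data.frame with `site_id`, coordinates, `mu`,
#'   `true_median`, `expected_olsen`, `method`; `coefficients`; `fates`
#'   per-record data.frame with `sample_id`, `fate`, `reason`), and `fields`
#'   (the internal world used, for reuse).
#' @export
generate_samples <- function(config = synth_config(),
                             registry = default_registry()) {
  stopifnot(inherits(config, "synth_config"))
  fl <- .synth_fields(config)
  n_total <- sum(config$n_sites)
  if (n_total < 1) stop("infeasible config: no sites")

  # --- site placement: uniform within the country strip, on land ----------
  sites <- list()
  ncty <- length(fl$countries)
  strip_w <- fl$nx / ncty * fl$res
  for (i in seq_len(ncty)) {
    m <- config$n_sites[i]
    got <- 0L
    lon <- numeric(0); lat <- numeric(0)
    while (got < m) {
      cand_lon <- stats::runif(2L * (m - got),
                               fl$xmin + (i - 1) * strip_w,
                               fl$xmin + i * strip_w)
      cand_lat <- stats::runif(2L * (m - got), fl$ymin,
                               fl$ymin + fl$ny * fl$res)
      ix <- floor((cand_lon - fl$xmin) / fl$res) + 1L
      iy <- floor((cand_lat - fl$ymin) / fl$res) + 1L
      ok <- fl$land[cbind(iy, ix)] == 1
      lon <- c(lon, cand_lon[ok]); lat <- c(lat, cand_lat[ok])
      got <- length(lon)
    }
    sites[[i]] <- data.frame(country = fl$countries[i],
                             longitude = lon[seq_len(m)],
                             latitude = lat[seq_len(m)],
                             stringsAsFactors = FALSE)
  }
  st <- do.call(rbind, sites)
  st$site_id <- sprintf("site_%04d", seq_len(n_total))
  ix <- floor((st$longitude - fl$xmin) / fl$res) + 1L
  iy <- floor((st$latitude - fl$ymin) / fl$res) + 1L
  cell <- cbind(iy, ix)
  st$cov1 <- fl$cov1[cell]; st$cov2 <- fl$cov2[cell]; st$cov3 <- fl$cov3[cell]
  st$pH <- fl$ph[cell]
  st$mu <- fl$mu[cell]
  st$eps <- if (config$sigma > 0) stats::rnorm(n_total, 0, config$sigma)
    else rep(0, n_total)
  st$olsen_true <- exp(st$mu + st$eps)   # site's realized Olsen value
  st$soil_class <- classify_calcareous(st$pH)
  st$year <- sample(seq(config$year_window[1], config$year_window[2]),
                    n_total, replace = TRUE)

  # --- method assignment (deterministic counts, seeded placement) ---------
  counts <- .alloc_counts(n_total, config$method_mix)
  ord <- sample(n_total)
  method <- rep("olsen", n_total)
  eq_for <- function(m, cls) {
    cmb <- registry$combined
    if (m %in% c("bray1", "kirsanov")) m <- "bray1"
    rows <- cmb[cmb$method == m, , drop = FALSE]
    if (nrow(rows) > 1L) rows <- rows[rows$soil_class == cls, , drop = FALSE]
    rows[1, , drop = FALSE]
  }
  # walk the shuffled site order once per converted method (rarest first so
  # small quotas are not starved); sites never picked stay Olsen
  pool <- ord
  conv_methods <- setdiff(names(counts), "olsen")
  for (m in conv_methods[order(counts[conv_methods])]) {
    need <- counts[[m]]
    taken <- logical(length(pool))
    for (j in seq_along(pool)) {
      if (need == 0L) break
      i <- pool[j]
      if (m %in% c("bray1", "kirsanov") && st$pH[i] >= 7) next
      eq <- eq_for(m, st$soil_class[i])
      # inversion must give a positive raw value clear of the detection
      # limit (a lab would not report below it)
      if (st$olsen_true[i] <= eq$intercept +
            eq$slope * config$detection_limit) next
      method[i] <- m
      taken[j] <- TRUE
      need <- need - 1L
    }
    pool <- pool[!taken]
  }
  st$method <- method

  # raw reported value: inverse of the conversion the pipeline will apply
  st$value <- st$olsen_true
  st$equation_id <- "identity"
  for (i in which(st$method != "olsen")) {
    eq <- eq_for(st$method[i], st$soil_class[i])
    st$value[i] <- (st$olsen_true[i] - eq$intercept) / eq$slope
    st$equation_id[i] <- eq$equation_id
  }
  # pipeline half-limit substitution also hits uncensored Olsen values that
  # happen to fall below the limit; the manifest expects that
  st$expected_olsen <- ifelse(
    st$method == "olsen" & st$olsen_true < config$detection_limit,
    config$detection_limit / 2, st$olsen_true)

  # --- censoring: below-detection records (olsen-method sites only) -------
  n_cens <- round(config$below_limit_frac * n_total)
  cens_pool <- which(st$method == "olsen")
  cens_idx <- utils::head(sample(cens_pool), n_cens)
  st$below_detection <- FALSE
  if (length(cens_idx)) {
    st$below_detection[cens_idx] <- TRUE
    st$value[cens_idx] <- stats::runif(length(cens_idx), 0,
                                       config$detection_limit)
    st$expected_olsen[cens_idx] <- config$detection_limit / 2
  }

  # --- expand to records: depth profiles -----------------------------------
  n_md <- round(config$multi_depth_frac * n_total)
  md_idx <- utils::head(sample(setdiff(seq_len(n_total), cens_idx)), n_md)
  is_md <- seq_len(n_total) %in% md_idx
  rec <- st[rep(seq_len(n_total), times = ifelse(is_md, 2L, 1L)), ]
  dup2 <- duplicated(rec$site_id)
  rec$depth_top <- ifelse(dup2, 15, 0)
  rec$depth_bottom <- ifelse(dup2, 25, ifelse(rec$site_id %in% st$site_id[md_idx], 15, 20))

  # --- duplicates ----------------------------------------------------------
  single <- setdiff(which(st$method == "olsen" & !is_md &
                            st$olsen_true > config$detection_limit),
                    cens_idx)
  single <- single[order(single)]
  pool <- sample(single)
  n_ex <- round(config$dup_exact_frac * n_total)
  n_cd <- round(config$dup_coord_frac * n_total)
  if (n_ex + n_cd > length(pool))
    stop("infeasible config: more duplicates than eligible records")
  ex_sites <- utils::head(pool, n_ex)
  cd_sites <- utils::head(setdiff(pool, ex_sites), n_cd)
  ex_rows <- rec[match(st$site_id[ex_sites], rec$site_id), , drop = FALSE]
  cd_rows <- rec[match(st$site_id[cd_sites], rec$site_id), , drop = FALSE]
  if (nrow(cd_rows)) {
    cd_rows$value <- cd_rows$value * 1.25
    # dedupe takes the arithmetic mean of the two olsen values at the site
    st$expected_olsen[cd_sites] <- st$olsen_true[cd_sites] * 1.125
  }
  rec <- rbind(rec, ex_rows, cd_rows)

  # --- contaminant records (planted fates) --------------------------------
  n_st <- round(config$contam_stannous * n_total)
  n_vol <- round(config$contam_volumetric * n_total)
  n_ow <- round(config$contam_off_window * n_total)
  n_ol <- round(config$contam_off_land * n_total)
  mk_contam <- function(k) {
    if (k == 0) return(NULL)
    base_i <- sample(n_total, k, replace = k > n_total)
    out <- st[base_i, , drop = FALSE]
    out$depth_top <- 0; out$depth_bottom <- 20
    out
  }
  contam <- list()
  c1 <- mk_contam(n_st)
  if (!is.null(c1)) { c1$assay <- "stannous_chloride"; c1$.reason <- "method"
    contam <- c(contam, list(c1)) }
  c2 <- mk_contam(n_vol)
  if (!is.null(c2)) { c2$unit <- "volumetric"; c2$.reason <- "unit"
    contam <- c(contam, list(c2)) }
  c3 <- mk_contam(n_ow)
  if (!is.null(c3)) { c3$year <- 1997L; c3$.reason <- "year"
    contam <- c(contam, list(c3)) }
  c4 <- mk_contam(n_ol)
  if (!is.null(c4)) {
    # place in the water block
    wb_cells <- which(fl$water, arr.ind = TRUE)
    pick <- wb_cells[sample(nrow(wb_cells), n_ol, replace = n_ol > nrow(wb_cells)), ,
                     drop = FALSE]
    c4$longitude <- fl$xmin + (pick[, 2] - 0.5) * fl$res
    c4$latitude <- fl$ymin + (pick[, 1] - 0.5) * fl$res
    c4$.reason <- "land_mask"
    contam <- c(contam, list(c4))
  }

  rec$assay <- "molybdenum_blue"
  rec$unit <- "mass"
  rec$.reason <- NA_character_
  if (length(contam)) {
    for (j in seq_along(contam)) {
      cc <- contam[[j]]
      if (is.null(cc$assay)) cc$assay <- "molybdenum_blue"
      if (is.null(cc$unit)) cc$unit <- "mass"
      cc$depth_top <- 0; cc$depth_bottom <- 20
      contam[[j]] <- cc[, names(rec)]
    }
    rec <- rbind(rec, do.call(rbind, contam))
  }

  rec$sample_id <- sprintf("rec_%05d", seq_len(nrow(rec)))
  rec$source_id <- paste0("src_", rec$country)
  rec$province <- NA_character_
  rec$land_use <- NA_character_

  samples <- rec[, c("source_id", "sample_id", "longitude", "latitude",
                     "year", "depth_top", "depth_bottom", "method", "assay",
                     "value", "unit", "below_detection", "pH", "soil_class",
                     "country", "province", "land_use")]
  rownames(samples) <- NULL

  fates <- data.frame(
    sample_id = rec$sample_id,
    fate = ifelse(is.na(rec$.reason), "kept", "discarded"),
    reason = rec$.reason, stringsAsFactors = FALSE)

  truth <- st[, c("site_id", "country", "longitude", "latitude", "year",
                  "cov1", "cov2", "cov3", "pH", "soil_class", "method",
                  "mu", "eps", "olsen_true", "expected_olsen")]
  truth$true_median <- exp(truth$mu)
  rownames(truth) <- NULL

  manifest <- list(
    truth = truth,
    coefficients = list(
      beta0 = config$beta0, sigma = config$sigma,
      link = "beta0 + 1.0*tanh(cov1) + 0.6*sin(2*cov2) + country_offset",
      country_offsets = stats::setNames(fl$offsets, fl$countries)),
    fates = fates)
  list(samples = samples, manifest = manifest, fields = fl)
}

#' Generate the synthetic predictor rasters, masks and region labels
#'
#' Builds the gridded world matching [generate_samples()] under the same
#' config: smooth covariate surfaces, pH, slope and elevation, a constant
#' bulk-density surface, the land mask, categorical country / continent /
#' biome / development grids with label maps, and the true concentration
#' surface `exp(mu)`. True regional stock totals are computed by exact
#' summation over land pixels and recorded in the returned truth element.
#'
#' @param config a [synth_config()].
#' @return list with `covariates` (named list of [p_grid]: cov1-cov3, pH,
#'   slope, elevation), `bulk_density`, `land_mask`, `labels` (country,
#'   continent, biome, development label [p_grid]s), `true_concentration`,
#'   and `truth` (list: `stock_by_country`, `stock_by_continent`,
#'   `global_stock_kt`).
#' @export
generate_rasters <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  fl <- .synth_fields(config)
  g <- function(m, labels = NULL)
    p_grid(m, xmin = fl$xmin, ymin = fl$ymin, res = fl$res, labels = labels)

  ncty <- length(fl$countries)
  country_labels <- stats::setNames(fl$countries, seq_len(ncty))
  cont_names <- unique(unname(fl$continent_of_country))
  cont_idx_of_cty <- match(fl$continent_of_country, cont_names)
  cont_mat <- matrix(cont_idx_of_cty[fl$country_idx], fl$ny, fl$nx)
  dev_names <- unique(unname(fl$development_of_country))
  dev_idx_of_cty <- match(fl$development_of_country, dev_names)
  dev_mat <- matrix(dev_idx_of_cty[fl$country_idx], fl$ny, fl$nx)

  conc <- exp(fl$mu)
  land_i <- which(fl$land == 1)
  lat_cell <- fl$ymin + (row(fl$land) - 0.5) * fl$res
  area <- cell_area_m2(lat_cell, fl$res)
  stock <- pixel_stock(conc[land_i], config$bulk_density, 0.2, area[land_i])
  cty <- fl$countries[fl$country_idx[land_i]]
  cont <- fl$continent_of_country[cty]
  by_cty <- tapply(stock, cty, sum)
  by_cont <- tapply(stock, cont, sum)

  list(
    covariates = list(
      cov1 = g(fl$cov1), cov2 = g(fl$cov2), cov3 = g(fl$cov3),
      pH = g(fl$ph), slope = g(fl$slope), elevation = g(fl$elev)),
    bulk_density = g(matrix(config$bulk_density, fl$ny, fl$nx)),
    land_mask = g(fl$land),
    labels = list(
      country = g(matrix(as.numeric(fl$country_idx), fl$ny, fl$nx),
                  labels = country_labels),
      continent = g(cont_mat, labels = stats::setNames(
        cont_names, seq_along(cont_names))),
      biome = g(matrix(as.numeric(fl$biome_idx), fl$ny, fl$nx),
                labels = fl$biome_labels),
      development = g(dev_mat, labels = stats::setNames(
        dev_names, seq_along(dev_names)))),
    true_concentration = g(conc),
    truth = list(
      stock_by_country = by_cty,
      stock_by_continent = by_cont,
      global_stock_kt = sum(stock)))
}

#' Build a stock table from synthetic rasters
#'
#' Convenience assembly of a [stock_grid()] over the land pixels of a
#' [generate_rasters()] world, with spherical cell areas and region labels.
#'
#' @param rasters output of [generate_rasters()].
#' @param concentration optional [p_grid] of concentrations (default the
#'   world's true surface).
#' @param s_ln optional log-scale SD for per-pixel CVs.
#' @return a `stock_grid` data.frame.
#' @export
stock_grid_from_rasters <- function(rasters, concentration = NULL,
                                    s_ln = NA_real_) {
  conc_g <- if (is.null(concentration)) rasters$true_concentration else
    concentration
  land <- rasters$land_mask
  cc <- grid_coords(land)
  on_land <- cc$value == 1
  lon <- cc$lon[on_land]; lat <- cc$lat[on_land]
  stock_grid(
    concentration = grid_extract(conc_g, lon, lat),
    bulk_density = grid_extract(rasters$bulk_density, lon, lat),
    area_m2 = cell_area_m2(lat, land$res),
    depth_m = 0.2,
    country = grid_extract(rasters$labels$country, lon, lat,
                           as_label = TRUE),
    continent = grid_extract(rasters$labels$continent, lon, lat,
                             as_label = TRUE),
    biome = grid_extract(rasters$labels$biome, lon, lat, as_label = TRUE),
    development = grid_extract(rasters$labels$development, lon, lat,
                               as_label = TRUE),
    s_ln = s_ln, lon = lon, lat = lat)
}
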