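#' Overlap weight of a sampled layer within the 0-20 cm target interval
#'
#' The raw weight is the fraction of the target interval covered by the
#' layer; a 15-25 cm sample therefore influences the 0-20 cm mean by a
#' quarter. When a bulk density is supplied the weight is multiplied by it,
#' so denser layers contribute proportionally more mass.
#'
#' @param depth_top,depth_bottom layer bounds, cm below surface
#'   (`depth_bottom > depth_top >= 0`); vectorized.
#' @param bulk_density kg m^-3 (optional; default 1 means equal density).
#' @param target_top,target_bottom target interval, cm (default 0-20).
#' @return numeric weight(s); 0 for layers entirely below the target.
#' @export
overlap_weight <- function(depth_top, depth_bottom, bulk_density = 1,
                           target_top = 0, target_bottom = 20) {
  stopifnot(all(depth_top >= 0), all(depth_bottom > depth_top),
            target_bottom > target_top, all(bulk_density > 0))
  frac <- pmax(0, pmin(depth_bottom, target_bottom) -
                  pmax(depth_top, target_top)) / (target_bottom - target_top)
  frac * bulk_density
}

#' Standardize a multi-depth profile to one 0-20 cm value
#'
#' Depth-weighted mean of the layer concentrations using [overlap_weight()]
#' (overlap fraction x bulk density), renormalized over the contributing
#' layers. The result is a convex combination of the inputs, independent of
#' layer order, and unchanged when a layer is split into contiguous
#' sub-layers of equal concentration and density.
#'
#' @param layers data.frame with `depth_top`, `depth_bottom`, `olsen_p` and
#'   optionally `bulk_density`.
#' @param target_top,target_bottom target interval, cm.
#' @param min_coverage in strict mode, the minimum fraction of the target
#'   interval the profile must cover (default 0 = any coverage accepted; the
#'   profile is taken as representative of the full interval).
#' @return list with `olsen_p_0_20`, `n_layers_used`, `coverage` (fraction of
#'   the interval covered), or `NULL` when no layer overlaps the target
#'   (profile entirely below 20 cm) or coverage is below `min_coverage`.
#' @export
harmonize_profile <- function(layers, target_top = 0, target_bottom = 20,
                              min_coverage = 0) {
  stopifnot(all(c("depth_top", "depth_bottom", "olsen_p") %in% names(layers)))
  bd <- if (is.null(layers$bulk_density)) rep(1, nrow(layers)) else
    ifelse(is.na(layers$bulk_density), 1, layers$bulk_density)
  w <- overlap_weight(layers$depth_top, layers$depth_bottom, bd,
                      target_top, target_bottom)
  use <- w > 0
  if (!any(use)) return(NULL)
  cover <- sum(pmax(0, pmin(layers$depth_bottom[use], target_bottom) -
                       pmax(layers$depth_top[use], target_top))) /
    (target_bottom - target_top)
  cover <- min(cover, 1)
  if (cover < min_coverage) return(NULL)
  list(olsen_p_0_20 = sum(w[use] * layers$olsen_p[use]) / sum(w[use]),
       n_layers_used = sum(use), coverage = cover)
}

#' Collapse duplicate records at a site
#'
#' Two-stage rule: exact duplicates (same coordinates, date and value) are
#' removed first; remaining multiple concentrations at the same coordinates
#' are replaced by their arithmetic mean. Coordinates are matched after
#' rounding to `coord_digits` decimal places (default 5, about 1 m).
#' Idempotent.
#'
#' @param samples data.frame with `longitude`, `latitude`, `olsen_p` and
#'   optionally `year` (used for the exact-duplicate stage).
#' @param coord_digits decimal places defining "the same coordinates".
#' @return data.frame with one row per site: coordinates, `olsen_p_0_20`
#'   (or mean of `olsen_p`), `year` (of the first record), and bookkeeping
#'   columns `n_merged` (records merged into the row) and `n_exact_dups`
#'   (exact duplicates removed).
#' @export
dedupe_samples <- function(samples, coord_digits = 5L) {
  val_col <- if ("olsen_p_0_20" %in% names(samples)) "olsen_p_0_20" else
    "olsen_p"
  stopifnot(val_col %in% names(samples))
  lon <- round(samples$longitude, coord_digits)
  lat <- round(samples$latitude, coord_digits)
  yr <- if (is.null(samples$year)) rep(NA_integer_, nrow(samples)) else
    samples$year
  exact_key <- paste(lon, lat, yr, signif(samples[[val_col]], 12))
  first <- !duplicated(exact_key)
  n_exact <- as.integer(table(exact_key)[exact_key[first]]) - 1L
  s <- samples[first, , drop = FALSE]
  lon <- lon[first]; lat <- lat[first]; yr <- yr[first]
  site_key <- paste(lon, lat)
  agg_val <- tapply(s[[val_col]], site_key, mean)
  agg_n <- tapply(rep(1L, nrow(s)), site_key, sum)
  agg_ex <- tapply(n_exact, site_key, sum)
  ord <- match(unique(site_key), names(agg_val))
  keep_first <- !duplicated(site_key)
  out <- s[keep_first, , drop = FALSE]
  out[[val_col]] <- as.numeric(agg_val[ord])
  out$n_merged <- as.integer(agg_n[ord])
  out$n_exact_dups <- as.integer(agg_ex[ord])
  rownames(out) <- NULL
  out
}

#' Harmonize a converted sample table to one value per site (Step 4)
#'
#' Groups records by site (rounded coordinates x year), depth-standardizes
#' each site's profile to 0-20 cm with [harmonize_profile()] (sites sampled
#' only below 20 cm are dropped), then removes duplicates with
#' [dedupe_samples()].
#'
#' @param records data.frame with `longitude`, `latitude`, `year`,
#'   `depth_top`, `depth_bottom`, `olsen_p` and optionally `bulk_density`.
#' @param coord_digits coordinate rounding for the site key.
#' @param min_coverage passed to [harmonize_profile()].
#' @return list with `samples` (one row per site: coordinates, `year`,
#'   `olsen_p_0_20`, `n_layers_used`, `coverage`, merge counters) and
#'   `dropped_deep_n` (sites discarded as entirely below 20 cm).
#' @export
harmonize_samples <- function(records, coord_digits = 5L, min_coverage = 0) {
  need <- c("longitude", "latitude", "year", "depth_top", "depth_bottom",
            "olsen_p")
  stopifnot(all(need %in% names(records)))
  records <- records[!is.na(records$olsen_p), , drop = FALSE]
  key <- paste(round(records$longitude, coord_digits),
               round(records$latitude, coord_digits), records$year)
  rows <- list()
  dropped <- 0L
  for (k in unique(key)) {
    grp <- records[key == k, , drop = FALSE]
    # records at identical depth intervals are duplicates within the profile:
    # keep them; the exact-duplicate stage of dedupe handles single-layer
    # sites, and equal layers average to themselves.
    h <- harmonize_profile(grp, min_coverage = min_coverage)
    if (is.null(h)) { dropped <- dropped + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      longitude = grp$longitude[1], latitude = grp$latitude[1],
      year = grp$year[1],
      country = if (is.null(grp$country)) NA_character_ else grp$country[1],
      olsen_p_0_20 = h$olsen_p_0_20, n_layers_used = h$n_layers_used,
      coverage = h$coverage, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(list(samples = data.frame(), dropped_deep_n = dropped))
  out <- do.call(rbind, rows)
  out <- dedupe_samples(out, coord_digits)
  list(samples = out, dropped_deep_n = dropped)
}

#' Quartile/fence outlier summary of a concentration set
#'
#' Box-plot bookkeeping used to audit each source database: quartiles by
#' linear interpolation between order statistics, fences at 1.5 interquartile
#' ranges beyond the quartiles, minor outliers strictly between the upper
#' quartile and upper fence, major outliers above the upper fence. Outliers
#' are summarized, never removed.
#'
#' @param values numeric vector, length >= 4.
#' @return list with `q25`, `q50`, `q75`, `iqr`, `lower_fence`,
#'   `upper_fence`, `minor_count`, `major_count`, `n`, `pct_major`.
#' @export
outlier_summary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 4) stop("insufficient data: need at least 4 values")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lower <- q[1] - 1.5 * iqr
  upper <- q[3] + 1.5 * iqr
  minor <- sum(values > q[3] & values < upper)
  major <- sum(values > upper)
  list(q25 = q[1], q50 = q[2], q75 = q[3], iqr = iqr,
       lower_fence = lower, upper_fence = upper,
       minor_count = minor, major_count = major,
       n = length(values), pct_major = 100 * major / length(values))
}
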