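#' Filtering configuration for the screening pipeline
#'
#' Bundles the screening rules applied to a raw multi-source soil-sample
#' table: the default assay detection limit, the acceptable sampling window,
#' sources exempt from it, and the special rules for the Chinese national
#' survey (minimum year and excluded eastern provinces, where land use
#' intensified after the survey).
#'
#' @param detection_limit_default default detection limit, mg P kg^-1.
#' @param year_window inclusive `[start, end]` calendar-year window.
#' @param exempt_sources `source_id` values allowed outside the window
#'   (long-stable land uses).
#' @param china_source_id `source_id` of the Chinese survey subject to the
#'   province/year rules (`NULL` to disable).
#' @param excluded_provinces provinces removed for that source.
#' @param china_min_year earliest acceptable year for that source.
#' @param land_mask optional [p_grid] with 1 = land, 0 = water/glacier/
#'   permanent snowpack; records off land (or where the mask is 0/NA) are
#'   discarded. `NULL` skips the mask check.
#' @param zero_coord_missing treat coordinates exactly (0, 0) as a
#'   missing-georeference placeholder (default `TRUE`).
#' @param at_limit_censored also substitute values exactly *at* the detection
#'   limit (default `FALSE`: only strictly-below or flagged values).
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(detection_limit_default = 2,
                          year_window = c(2000L, 2019L),
                          exempt_sources = character(),
                          china_source_id = NULL,
                          excluded_provinces = c(
                            "Anhui", "Fujian", "Guangdong", "Guangxi",
                            "Hainan", "Hebei", "Jiangsu", "Jiangxi",
                            "Shandong", "Sichuan", "Tianjin"),
                          china_min_year = 1995L,
                          land_mask = NULL,
                          zero_coord_missing = TRUE,
                          at_limit_censored = FALSE) {
  stopifnot(detection_limit_default > 0,
            length(year_window) == 2, year_window[1] <= year_window[2])
  structure(
    list(detection_limit_default = detection_limit_default,
         year_window = as.integer(year_window),
         exempt_sources = exempt_sources,
         china_source_id = china_source_id,
         excluded_provinces = excluded_provinces,
         china_min_year = as.integer(china_min_year),
         land_mask = land_mask,
         zero_coord_missing = zero_coord_missing,
         at_limit_censored = at_limit_censored),
    class = "filter_config")
}

#' Read a canonical soil-sample table
#'
#' Reads the package's canonical CSV schema (one row per measurement; columns
#' named after the sample-record fields: `source_id`, `sample_id`,
#' `longitude`, `latitude`, `year`, `depth_top`, `depth_bottom`, `method`,
#' `assay`, `value`, `unit`, `below_detection`, `pH`, `soil_class`,
#' `country`, `province`, `land_use`). Missing optional columns are added as
#' `NA`; `assay`/`unit`/`soil_class` default to `unknown`/`mass`/`unknown`.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_soil_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("source_id", "sample_id", "longitude", "latitude", "year",
           "depth_top", "depth_bottom", "method", "value")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (is.null(df$assay)) df$assay <- "unknown"
  if (is.null(df$unit)) df$unit <- "mass"
  if (is.null(df$below_detection)) df$below_detection <- FALSE
  if (is.null(df$pH)) df$pH <- NA_real_
  if (is.null(df$soil_class)) df$soil_class <- "unknown"
  if (is.null(df$country)) df$country <- NA_character_
  if (is.null(df$province)) df$province <- NA_character_
  if (is.null(df$land_use)) df$land_use <- NA_character_
  df$below_detection <- as.logical(df$below_detection)
  df
}

#' Method, assay and unit screen (Step 1)
#'
#' Keeps measurements whose assay chemistry is comparable (molybdenum blue
#' colorimetry, ion chromatography, or unreported) and whose unit is mass
#' based (mg P kg^-1); discards stannous-chloride assays and volumetric
#' (mg L^-1) records. Records with a missing concentration are rejected as
#' malformed.
#'
#' @param records data.frame with at least `assay`, `unit`, `value`.
#' @return data.frame with one row per record: `keep` (logical) and `reason`
#'   (`NA` when kept; otherwise `"malformed"`, `"method"` or `"unit"`).
#' @export
screen_method <- function(records) {
  stopifnot(all(c("assay", "unit", "value") %in% names(records)))
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  reason[is.na(records$value)] <- "malformed"
  bad_assay <- is.na(reason) & records$assay %in% "stannous_chloride"
  reason[bad_assay] <- "method"
  bad_unit <- is.na(reason) & records$unit %in% "volumetric"
  reason[bad_unit] <- "unit"
  data.frame(keep = is.na(reason), reason = reason,
             stringsAsFactors = FALSE)
}

#' Infer an unreported detection limit from repeated low values
#'
#' Sources that censor at an unreported detection limit typically substitute
#' a fixed low value (half the limit) many times. The inferred half-limit is
#' the smallest value that (i) repeats at least `repeat_threshold` times,
#' (ii) lies within the lowest decile of the source's values, and (iii) is
#' strictly below the source median (so a constant-valued source yields
#' nothing). The implied detection limit is twice that value.
#'
#' @param values numeric vector of one source's concentrations, mg kg^-1.
#' @param repeat_threshold minimum repetition count (default 10).
#' @return `NULL` if no such value; otherwise a list with `half_limit` (the
#'   repeated value) and `implied_limit` (= 2 x half_limit).
#' @export
infer_detection_limit <- function(values, repeat_threshold = 10L) {
  stopifnot(repeat_threshold >= 2L)
  values <- values[!is.na(values)]
  if (!length(values)) return(NULL)
  tab <- table(values)
  cand <- as.numeric(names(tab)[tab >= repeat_threshold])
  q10 <- stats::quantile(values, 0.10, names = FALSE)
  med <- stats::median(values)
  cand <- cand[cand <= q10 & cand < med]
  if (!length(cand)) return(NULL)
  half <- min(cand)
  list(half_limit = half, implied_limit = 2 * half)
}

#' Substitute censored values by half the detection limit
#'
#' Values below the detection limit (or flagged as censored) are replaced by
#' half the limit, the conventional treatment for left-censored environmental
#' concentrations. Never increases a value and is idempotent.
#'
#' @param value concentrations, mg kg^-1 (non-negative).
#' @param below_detection logical flag(s), recycled.
#' @param limit detection limit, mg kg^-1 (> 0), recycled.
#' @param at_limit also substitute values exactly at the limit.
#' @return numeric vector of adjusted concentrations.
#' @export
substitute_detection_limit <- function(value, below_detection = FALSE,
                                       limit = 2, at_limit = FALSE) {
  if (any(limit <= 0)) stop("detection limit must be positive")
  if (any(value < 0, na.rm = TRUE)) stop("invalid concentration")
  cens <- below_detection | value < limit |
    (if (isTRUE(at_limit)) value == limit else FALSE)
  ifelse(!is.na(cens) & cens, limit / 2, value)
}

#' Geographic and temporal screen (Step 2)
#'
#' Discards records with missing or invalid coordinates (`georeference`),
#' records off land per the configured mask (`land_mask`), records outside
#' the sampling-year window unless their source is exempt (`year`), and — for
#' the configured Chinese survey source — records from excluded eastern
#' provinces (`province`) or sampled before the survey's minimum year
#' (`year`).
#'
#' @param records data.frame with `source_id`, `longitude`, `latitude`,
#'   `year` and (optionally) `province`.
#' @param config a [filter_config].
#' @return data.frame with `keep` and `reason` per record.
#' @export
filter_geotemporal <- function(records, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  lon <- records$longitude
  lat <- records$latitude
  bad_geo <- is.na(lon) | is.na(lat) | abs(lat) > 90 | abs(lon) > 180
  if (config$zero_coord_missing)
    bad_geo <- bad_geo | (!is.na(lon) & !is.na(lat) & lon == 0 & lat == 0)
  reason[bad_geo] <- "georeference"
  if (!is.null(config$land_mask)) {
    land <- grid_extract(config$land_mask, lon, lat)
    off <- is.na(reason) & (is.na(land) | land == 0)
    reason[off] <- "land_mask"
  }
  is_china <- if (is.null(config$china_source_id)) rep(FALSE, n) else
    records$source_id %in% config$china_source_id
  prov <- if (is.null(records$province)) rep(NA_character_, n) else
    records$province
  bad_prov <- is.na(reason) & is_china & prov %in% config$excluded_provinces
  reason[bad_prov] <- "province"
  exempt <- records$source_id %in% config$exempt_sources | is_china
  in_window <- !is.na(records$year) &
    records$year >= config$year_window[1] &
    records$year <= config$year_window[2]
  bad_year <- is.na(reason) & ((!exempt & !in_window) |
    (is_china & (is.na(records$year) | records$year < config$china_min_year)))
  reason[bad_year] <- "year"
  data.frame(keep = is.na(reason), reason = reason,
             stringsAsFactors = FALSE)
}

#' Run the full screening stage with an audit trail
#'
#' Applies [screen_method()] then [filter_geotemporal()] to a raw sample
#' table, substitutes censored values on the surviving records (per-source
#' limits from `manifest` when given, inferred from repeated low values
#' otherwise, else the configured default), and returns the annotated table
#' together with a conservation-checked filter report.
#'
#' @param records raw sample data.frame (see [read_soil_samples()]).
#' @param config a [filter_config].
#' @param manifest optional data.frame (`source_id`, `detection_limit`)
#'   of known per-source limits.
#' @param repeat_threshold passed to [infer_detection_limit()].
#' @return list with `records` (input plus `filter_status` = kept/discarded,
#'   `filter_reason`, and `value` censor-substituted on kept rows) and
#'   `report` (see [filter_report()]).
#' @export
filter_samples <- function(records, config = filter_config(),
                           manifest = NULL, repeat_threshold = 10L) {
  n0 <- nrow(records)
  s1 <- screen_method(records)
  s2 <- filter_geotemporal(records, config)
  reason <- ifelse(!s1$keep, s1$reason, ifelse(!s2$keep, s2$reason, NA))
  keep <- is.na(reason)
  records$filter_status <- ifelse(keep, "kept", "discarded")
  records$filter_reason <- reason

  # per-source detection limits: manifest > inferred > default
  limits <- stats::setNames(
    rep(config$detection_limit_default, 0), character())
  for (src in unique(records$source_id[keep])) {
    lim <- NA_real_
    if (!is.null(manifest) && src %in% manifest$source_id)
      lim <- manifest$detection_limit[match(src, manifest$source_id)]
    if (is.na(lim)) {
      inf <- infer_detection_limit(records$value[keep & records$source_id == src],
                                   repeat_threshold)
      lim <- if (is.null(inf)) config$detection_limit_default else
        inf$implied_limit
    }
    limits[src] <- lim
  }
  bd <- records$below_detection
  if (is.null(bd)) bd <- rep(FALSE, n0)
  bd[is.na(bd)] <- FALSE
  records$value[keep] <- substitute_detection_limit(
    records$value[keep], bd[keep],
    limit = unname(limits[records$source_id[keep]]),
    at_limit = config$at_limit_censored)

  report <- filter_report(n0, reason)
  list(records = records, report = report,
       detection_limits = limits)
}

#' Build a filter report from discard reasons
#'
#' @param input_n number of input records.
#' @param reason character vector of discard reasons (`NA` = kept).
#' @return list with `input_n`, `kept_n`, `discarded_n` and a named
#'   `discarded_by_reason` vector; satisfies
#'   `input_n == kept_n + sum(discarded_by_reason)`.
#' @export
filter_report <- function(input_n, reason) {
  disc <- table(reason[!is.na(reason)])
  rep_ <- list(input_n = as.integer(input_n),
               kept_n = as.integer(sum(is.na(reason))),
               discarded_n = as.integer(sum(!is.na(reason))),
               discarded_by_reason = as.list(
                 stats::setNames(as.integer(disc), names(disc))))
  stopifnot(rep_$input_n == rep_$kept_n + rep_$discarded_n)
  rep_
}

#' Write a filter report as JSON
#'
#' @param report list from [filter_report()] (or the `report` element of
#'   [filter_samples()]).
#' @param path output path.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
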