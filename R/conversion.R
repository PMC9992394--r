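#' Construct a linear soil-test conversion equation
#'
#' An equation `olsen = slope * x + intercept` mapping a source soil-test
#' value `x` (mg P kg^-1) to Olsen P, valid for a soil class, together with
#' the sample size and fit quality of the regression it came from.
#'
#' @param method one of `"bray1"`, `"mehlich3"`, `"resin"`, `"kirsanov"`,
#'   `"abdpta"`, `"olsen"`.
#' @param soil_class `"calcareous"`, `"non_calcareous"` or `"any"`.
#' @param slope,intercept regression coefficients (slope > 0).
#' @param r_squared coefficient of determination in `[0, 1]` (or `NA`).
#' @param n_samples number of soil samples behind the regression.
#' @param jurisdiction,source_ref provenance strings.
#' @param equation_id identifier (auto-built when `NULL`).
#' @return one-row data.frame.
#' @export
conversion_equation <- function(method, soil_class, slope, intercept,
                                r_squared = NA_real_, n_samples = 1L,
                                jurisdiction = "", source_ref = "",
                                equation_id = NULL) {
  stopifnot(slope > 0, n_samples >= 1,
            is.na(r_squared) || (r_squared >= 0 && r_squared <= 1))
  if (is.null(equation_id))
    equation_id <- paste(method, soil_class, jurisdiction, n_samples,
                         sep = "_")
  data.frame(equation_id = equation_id, method = method,
             soil_class = soil_class, slope = slope, intercept = intercept,
             r_squared = r_squared, n_samples = as.integer(n_samples),
             jurisdiction = jurisdiction, source_ref = source_ref,
             stringsAsFactors = FALSE)
}

# Published component regressions, one row per source study.
.component_equations <- function() {
  rbind(
    conversion_equation("mehlich3", "non_calcareous", 0.33,  6.9, 0.88,  91, "US"),
    conversion_equation("mehlich3", "non_calcareous", 0.47,  1.2, 0.79, 180, "US"),
    conversion_equation("mehlich3", "calcareous",     0.45,  1.8, 0.81,  60, "US"),
    conversion_equation("mehlich3", "non_calcareous", 0.70, -0.6, 0.71,  66, "Italy"),
    conversion_equation("mehlich3", "calcareous",     0.37,  0.4, 0.73,  54, "Italy"),
    conversion_equation("bray1",    "non_calcareous", 0.43,  2.4, 0.68, 180, "US"),
    conversion_equation("bray1",    "non_calcareous", 0.68,  3.9, 0.95, 165, "US"),
    conversion_equation("bray1",    "non_calcareous", 0.30,  2.9, 0.85,  91, "US"),
    conversion_equation("abdpta",   "any",            1.81,  4.1, 0.50,  35, "India"),
    conversion_equation("resin",    "non_calcareous", 0.71,  0.1, 0.91,  59, "US"),
    conversion_equation("resin",    "calcareous",     0.94,  0.0, NA,    30, "US"))
}

#' Sample-size-weighted mean of conversion equations
#'
#' Combines several published regressions for the same soil test and soil
#' class into one equation by weighting slope, intercept and R^2 by each
#' regression's sample size; the combined sample size is the sum. The result
#' is a convex combination, so each coefficient lies within the range of its
#' components. Full precision is retained (round for display only).
#'
#' @param equations data.frame of [conversion_equation()] rows sharing
#'   `method` (and, for class-split tests, `soil_class`).
#' @return one-row combined equation.
#' @export
weighted_mean_equation <- function(equations) {
  if (!nrow(equations)) stop("no equations to combine")
  if (length(unique(equations$method)) != 1L)
    stop("incompatible equations: mixed methods")
  w <- equations$n_samples
  wm <- function(x) {
    ok <- !is.na(x)
    if (!any(ok)) return(NA_real_)
    sum(w[ok] * x[ok]) / sum(w[ok])
  }
  cls <- unique(equations$soil_class)
  conversion_equation(
    method = equations$method[1],
    soil_class = if (length(cls) == 1L) cls else "any",
    slope = wm(equations$slope),
    intercept = wm(equations$intercept),
    r_squared = wm(equations$r_squared),
    n_samples = sum(w),
    jurisdiction = "combined",
    equation_id = paste0(equations$method[1], "_",
                         if (length(cls) == 1L) cls else "any", "_combined"))
}

#' The default conversion registry
#'
#' Holds the published component regressions and the combined (weighted-mean)
#' equations used for conversion, plus the routing rules: Bray-I (and, by
#' extension, Kirsanov, whose 0.2 N HCl extractant Bray-I approximates) is
#' rejected on soils with pH >= 7 because the acid extractant dissolves
#' calcium phosphates of little plant availability; Mehlich-3 and Resin route
#' by calcareous class; AB-DPTA has a single class-free equation.
#'
#' With `printed = TRUE` (default) the combined coefficients are the
#' published rounded values (e.g. Olsen = 0.49 x Bray-I + 3.1), the form in
#' which the conversion tool circulates; `printed = FALSE` recombines the
#' component rows at full precision via [weighted_mean_equation()].
#'
#' @param printed use published rounded combined coefficients.
#' @return list of class `conversion_registry` with elements `components`,
#'   `combined`, `bray_ph_cutoff` (7), `kirsanov_as_bray` (TRUE).
#' @export
default_registry <- function(printed = TRUE) {
  comp <- .component_equations()
  if (printed) {
    combined <- rbind(
      conversion_equation("mehlich3", "non_calcareous", 0.47, 2.4, 0.80, 337,
                          "combined", equation_id = "mehlich3_non_calcareous_combined"),
      conversion_equation("mehlich3", "calcareous",     0.41, 1.1, 0.77, 114,
                          "combined", equation_id = "mehlich3_calcareous_combined"),
      conversion_equation("bray1",    "any",            0.49, 3.1, 0.82, 436,
                          "combined", equation_id = "bray1_any_combined"),
      conversion_equation("abdpta",   "any",            1.81, 4.1, 0.50,  35,
                          "combined", equation_id = "abdpta_any_combined"),
      conversion_equation("resin",    "non_calcareous", 0.71, 0.1, 0.91,  59,
                          "combined", equation_id = "resin_non_calcareous_combined"),
      conversion_equation("resin",    "calcareous",     0.94, 0.0, NA,    30,
                          "combined", equation_id = "resin_calcareous_combined"))
  } else {
    combined <- build_combined(comp)
  }
  structure(list(components = comp, combined = combined,
                 bray_ph_cutoff = 7, kirsanov_as_bray = TRUE),
            class = "conversion_registry")
}

#' Recombine component equations into the combined table
#'
#' Groups component rows by (method, soil class) — Bray-I rows pooled across
#' class into a single equation, matching how the published weighted mean is
#' formed — and applies [weighted_mean_equation()] to each group.
#'
#' @param components data.frame of component equations.
#' @return data.frame of combined equations.
#' @export
build_combined <- function(components) {
  out <- list()
  for (m in unique(components$method)) {
    rows <- components[components$method == m, , drop = FALSE]
    if (m %in% c("bray1", "abdpta")) {
      eq <- weighted_mean_equation(rows)
      eq$soil_class <- "any"
      eq$equation_id <- paste0(m, "_any_combined")
      out[[length(out) + 1L]] <- eq
    } else {
      for (cls in unique(rows$soil_class)) {
        sub <- rows[rows$soil_class == cls, , drop = FALSE]
        out[[length(out) + 1L]] <- weighted_mean_equation(sub)
      }
    }
  }
  do.call(rbind, out)
}

#' Build a registry from a component-equation CSV
#'
#' @param path CSV with columns `method`, `soil_class`, `slope`, `intercept`,
#'   `r_squared`, `n_samples`, `jurisdiction` (extra columns ignored).
#' @param bray_ph_cutoff pH at and above which Bray-I/Kirsanov records are
#'   rejected.
#' @return `conversion_registry`.
#' @export
build_registry <- function(path, bray_ph_cutoff = 7) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  comp <- do.call(rbind, lapply(seq_len(nrow(df)), function(i)
    conversion_equation(df$method[i], df$soil_class[i], df$slope[i],
                        df$intercept[i],
                        if (is.null(df$r_squared)) NA else df$r_squared[i],
                        df$n_samples[i],
                        if (is.null(df$jurisdiction)) "" else df$jurisdiction[i])))
  structure(list(components = comp, combined = build_combined(comp),
                 bray_ph_cutoff = bray_ph_cutoff, kirsanov_as_bray = TRUE),
            class = "conversion_registry")
}

#' Classify a soil as calcareous or not
#'
#' Used when the record carries no calcareous flag: calcareous when pH at or
#' above the cutoff (free carbonate keeps soil pH near or above neutral),
#' otherwise non-calcareous; unknown pH defaults to non-calcareous.
#'
#' @param pH soil pH (may be NA).
#' @param cutoff pH threshold (default 7.5).
#' @return `"calcareous"` or `"non_calcareous"` (vectorized).
#' @export
classify_calcareous <- function(pH, cutoff = 7.5) {
  ifelse(!is.na(pH) & pH >= cutoff, "calcareous", "non_calcareous")
}

#' Resolve the conversion equation for one record
#'
#' Routing: Olsen measurements need no conversion (identity); Bray-I — and
#' Kirsanov, aliased to the combined Bray-I equation — are rejected at
#' pH >= 7 (the registry cutoff); Mehlich-3 and Resin take the
#' class-specific combined equation (records of unknown class routed through
#' [classify_calcareous()]); AB-DPTA takes its single equation.
#'
#' @param method soil-test method string.
#' @param soil_class `"calcareous"`, `"non_calcareous"` or `"unknown"`.
#' @param pH soil pH (NA allowed except where the pH gate applies).
#' @param registry a `conversion_registry`.
#' @return list with `status` (`"ok"` or `"reject"`), `reason` (`NA` or
#'   `"pH"`), and `equation` (one-row data.frame; identity for Olsen).
#' @export
resolve_equation <- function(method, soil_class = "unknown", pH = NA,
                             registry = default_registry()) {
  stopifnot(inherits(registry, "conversion_registry"))
  if (method == "olsen") {
    return(list(status = "ok", reason = NA_character_,
                equation = conversion_equation(
                  "olsen", "any", 1, 0, n_samples = 1L,
                  equation_id = "identity")))
  }
  lookup_method <- method
  if (method == "kirsanov") {
    if (!isTRUE(registry$kirsanov_as_bray))
      stop("no conversion available for kirsanov")
    lookup_method <- "bray1"
  }
  if (lookup_method == "bray1" && !is.na(pH) && pH >= registry$bray_ph_cutoff)
    return(list(status = "reject", reason = "pH", equation = NULL))
  comb <- registry$combined[registry$combined$method == lookup_method, ,
                            drop = FALSE]
  if (!nrow(comb)) stop("no conversion available for ", method)
  if (nrow(comb) > 1L) {
    cls <- if (identical(soil_class, "unknown") || is.na(soil_class))
      classify_calcareous(pH) else soil_class
    comb <- comb[comb$soil_class %in% c(cls, "any"), , drop = FALSE]
    if (!nrow(comb)) stop("no conversion available for ", method, "/", cls)
  }
  list(status = "ok", reason = NA_character_,
       equation = comb[1, , drop = FALSE])
}

#' Apply a conversion equation
#'
#' `olsen = slope * value + intercept`, floored at zero (a safety net: all
#' combined equations have non-negative intercepts so the floor never
#' triggers for them on non-negative input).
#'
#' @param value source-test concentration(s), mg kg^-1, non-negative.
#' @param equation one-row equation data.frame.
#' @return Olsen P, mg kg^-1, with the equation id attached as attribute
#'   `equation_id`.
#' @export
to_olsen <- function(value, equation) {
  if (any(value < 0, na.rm = TRUE)) stop("value must be non-negative")
  out <- pmax(0, equation$slope * value + equation$intercept)
  attr(out, "equation_id") <- equation$equation_id
  out
}

#' Convert a filtered sample table to Olsen P (Step 3)
#'
#' Resolves and applies the conversion equation row by row, adding `olsen_p`,
#' `converted_from` and `equation_id` columns. Bray-I/Kirsanov records on
#' soils with pH at or above the registry cutoff are flagged
#' `convert_status = "rejected_ph"` and get `NA` Olsen values.
#'
#' @param records data.frame with `method`, `value`, and optionally `pH`,
#'   `soil_class`.
#' @param registry a `conversion_registry`.
#' @return the input with conversion columns appended.
#' @export
convert_samples <- function(records, registry = default_registry()) {
  n <- nrow(records)
  pH <- if (is.null(records$pH)) rep(NA_real_, n) else records$pH
  cls <- if (is.null(records$soil_class)) rep("unknown", n) else
    records$soil_class
  olsen <- rep(NA_real_, n)
  eqid <- rep(NA_character_, n)
  status <- rep("converted", n)
  # resolve once per (method, class, pH-gate) stratum, then apply vectorized
  gate <- !is.na(pH) & pH >= registry$bray_ph_cutoff
  cls_eff <- ifelse(is.na(cls) | cls == "unknown",
                    classify_calcareous(pH), cls)
  key <- paste(records$method, cls_eff, gate)
  for (k in unique(key)) {
    idx <- which(key == k)
    i <- idx[1]
    res <- resolve_equation(records$method[i], cls_eff[i], pH[i], registry)
    if (res$status == "reject") {
      status[idx] <- "rejected_ph"
      next
    }
    olsen[idx] <- as.numeric(to_olsen(records$value[idx], res$equation))
    eqid[idx] <- res$equation$equation_id
    if (records$method[i] == "olsen") status[idx] <- "identity"
  }
  records$olsen_p <- olsen
  records$converted_from <- records$method
  records$equation_id <- eqid
  records$convert_status <- status
  records
}

#' Validate a conversion equation against paired measurements
#'
#' Regresses measured Olsen P on the equation's predictions (ordinary least
#' squares) and reports the slope, intercept, slope p-value and
#' Nash-Sutcliffe efficiency. A conversion fit for purpose has slope near 1
#' and high NSE.
#'
#' @param source_values source-test concentrations, mg kg^-1.
#' @param measured_olsen paired measured Olsen P, mg kg^-1.
#' @param equation the conversion equation under test.
#' @return list with `slope`, `intercept`, `p_value`, `nse`, `n`.
#' @export
validate_conversion <- function(source_values, measured_olsen, equation) {
  stopifnot(length(source_values) == length(measured_olsen),
            length(source_values) >= 3)
  predicted <- as.numeric(to_olsen(source_values, equation))
  if (stats::sd(predicted) == 0) stop("no variance in predictions")
  fit <- stats::lm(measured_olsen ~ predicted)
  sm <- summary(fit)
  nse <- 1 - sum((measured_olsen - predicted)^2) /
    sum((measured_olsen - mean(measured_olsen))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p_value = unname(sm$coefficients[2, 4]),
       nse = nse, n = length(predicted))
}

#' Write a registry's component equations to CSV
#'
#' @param registry a `conversion_registry`.
#' @param path output CSV.
#' @export
write_registry_csv <- function(registry, path) {
  utils::write.csv(registry$components, path, row.names = FALSE)
  invisible(path)
}
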