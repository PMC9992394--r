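#' Pair harmonized samples with gridded predictors
#'
#' Nearest-cell extraction of every predictor surface at the sample
#' coordinates. Rows where any covariate is missing (sample outside a grid's
#' extent, or a masked cell) are flagged and excluded from the usable table.
#'
#' @param samples data.frame with `longitude`, `latitude` (other columns
#'   carried through).
#' @param grids named list of [p_grid] predictor surfaces; names become
#'   covariate columns.
#' @return list with `table` (complete rows only), `flagged` (rows with
#'   missing coverage), `n_flagged`.
#' @export
extract_predictors <- function(samples, grids) {
  stopifnot(length(grids) > 0, !is.null(names(grids)),
            all(nzchar(names(grids))))
  out <- samples
  for (nm in names(grids)) {
    g <- grids[[nm]]
    out[[nm]] <- if (!is.null(g$labels))
      grid_extract(g, samples$longitude, samples$latitude, as_label = TRUE)
    else grid_extract(g, samples$longitude, samples$latitude)
  }
  newcols <- names(grids)
  ok <- stats::complete.cases(out[, newcols, drop = FALSE])
  list(table = out[ok, , drop = FALSE],
       flagged = out[!ok, , drop = FALSE],
       n_flagged = sum(!ok))
}

#' Reduce correlated covariates by principal components
#'
#' Column-standardized PCA keeping the smallest leading set of components
#' whose cumulative explained variance reaches `variance_target`. Used to
#' collapse families of autocorrelated monthly covariates before model
#' fitting, guarding against overfitting.
#'
#' @param X numeric matrix or data.frame (>= 2 columns), no missing values.
#' @param variance_target fraction of variance to retain (default 0.95).
#' @return list with `scores` (n x k matrix, columns `PC1..PCk`),
#'   `loadings`, `var_share` (all components; sums to 1), `cum_share`, `k`,
#'   and `center`/`scale` for projecting new data via [pca_project()].
#' @export
pca_reduce <- function(X, variance_target = 0.95) {
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 2, !anyNA(X),
            variance_target > 0, variance_target <= 1)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero variance predictor: ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  share <- pc$sdev^2 / sum(pc$sdev^2)
  cum <- cumsum(share)
  k <- which(cum >= variance_target - 1e-12)[1]
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       var_share = share, cum_share = cum, k = k,
       center = pc$center, scale = pc$scale)
}

#' Project new rows onto retained principal components
#'
#' @param pca result of [pca_reduce()].
#' @param X new data with the same columns.
#' @return n x k score matrix.
#' @export
pca_project <- function(pca, X) {
  X <- as.matrix(X)
  scale(X, center = pca$center, scale = pca$scale) %*% pca$loadings
}

#' Relabel a random 5% of each country as "other"
#'
#' Countries absent from the training data cannot receive a country effect at
#' prediction time. The device: a seeded random sample of a fixed fraction of
#' each country's rows has its country relabeled `"other"`, so the fitted
#' "other" level is a data-weighted average country effect usable for unseen
#' countries. Counts are rounded half away from zero, so countries with fewer
#' than `1/(2*fraction)` rows contribute nothing. No numeric covariate is
#' touched.
#'
#' @param table data.frame with a `country` column.
#' @param fraction fraction per country in (0, 1) (default 0.05).
#' @param seed integer seed for the row sampling.
#' @param append if `TRUE`, append relabeled copies instead of relabeling in
#'   place (default `FALSE`: rename in place).
#' @return the table with some `country` entries set to `"other"` (or extra
#'   rows appended); attribute `n_other` gives the relabeled-row count.
#' @export
other_country_augment <- function(table, fraction = 0.05, seed = 1L,
                                  append = FALSE) {
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  stopifnot("country" %in% names(table))
  set.seed(seed)
  picked <- integer(0)
  for (ctry in unique(table$country)) {
    idx <- which(table$country == ctry)
    m <- floor(fraction * length(idx) + 0.5)  # half away from zero
    if (m > 0) picked <- c(picked, sample(idx, m))
  }
  if (append) {
    extra <- table[picked, , drop = FALSE]
    if (length(picked)) extra$country <- "other"
    out <- rbind(table, extra)
  } else {
    out <- table
    out$country[picked] <- "other"
  }
  attr(out, "n_other") <- length(picked)
  out
}

#' Smearing retransformation-bias correction factor
#'
#' Predictions from a model of log concentration, naively exponentiated,
#' estimate the conditional median, not the mean. The nonparametric smearing
#' factor `S = mean(exp(residuals))` rescales them to the mean under
#' homoscedastic residuals. For mean-zero residuals, Jensen's inequality
#' gives `S >= 1`.
#'
#' @param residuals log-scale model residuals (length >= 1).
#' @return S (unitless, positive).
#' @export
smearing_factor <- function(residuals) {
  if (!length(residuals) || anyNA(residuals))
    stop("residuals must be non-empty and complete")
  mean(exp(residuals))
}

#' Performance metrics for concentration predictions
#'
#' R^2 as the squared Pearson correlation (in percent) and Nash-Sutcliffe
#' efficiency `1 - sum((o - p)^2) / sum((o - mean(o))^2)`; NSE is 1 for a
#' perfect match and 0 for a predictor no better than the observed mean. AIC
#' is carried through from the fitted model object when supplied.
#'
#' @param observed,predicted equal-length numeric vectors (n >= 3).
#' @param aic optional AIC of the generating fit.
#' @return list with `r_squared` (%), `nse`, `aic`, `n`.
#' @export
model_metrics <- function(observed, predicted, aic = NA_real_) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 3)
  if (stats::sd(observed) == 0) stop("zero variance in observed values")
  r2 <- if (stats::sd(predicted) == 0) NA_real_ else
    100 * stats::cor(observed, predicted)^2
  nse <- 1 - sum((observed - predicted)^2) /
    sum((observed - mean(observed))^2)
  list(r_squared = r2, nse = nse, aic = aic, n = length(observed))
}

#' Fit the log-scale additive concentration model
#'
#' Fits `log(olsen_p) ~ s(covariate_1) + ... + factor terms` with
#' [mgcv::gam()]. The log response is checked for approximate normality
#' (Shapiro-Wilk on the response, subsampled at 5000 for large n; the fit
#' proceeds regardless, with a warning when the statistic is low). With
#' `split_fraction` set, a seeded random share of rows trains the model and
#' the remainder evaluates it; with `NULL` the model uses all rows and is
#' evaluated in-sample (the configuration used for a final all-data model).
#' The smearing factor is computed from the training residuals and applied to
#' all back-transformed predictions.
#'
#' @param table data.frame containing the response and all predictors.
#' @param smooth_vars names of continuous covariates to enter as smooth
#'   terms (principal-component scores included here).
#' @param factor_vars names of categorical covariates (factor terms);
#'   a `country` column listed here receives the `"other"` routing at
#'   prediction time.
#' @param response name of the (strictly positive) concentration column.
#' @param split_fraction training fraction in (0, 1], or `NULL` for all-data.
#' @param seed seed for the train/test split.
#' @param shapiro_warn_w warn when the Shapiro-Wilk W of the log response
#'   falls below this (default 0.95).
#' @return object of class `olsen_fit`: list with the `gam` model,
#'   `smearing`, log-scale training `residuals`, `resid_sd`, `shapiro_w`,
#'   `metrics` (concentration-scale R^2/NSE on the evaluation rows, AIC from
#'   the gam), `train_idx`, `factor_levels`, and the term specification.
#' @export
fit_olsen_model <- function(table, smooth_vars, factor_vars = character(),
                            response = "olsen_p_0_20",
                            split_fraction = NULL, seed = 1L,
                            shapiro_warn_w = 0.95) {
  stopifnot(response %in% names(table),
            all(smooth_vars %in% names(table)),
            all(factor_vars %in% names(table)))
  y_all <- table[[response]]
  if (any(is.na(y_all)) || any(y_all <= 0))
    stop("response must be complete and strictly positive")
  ylog <- log(y_all)

  sw_y <- if (length(ylog) > 5000) {
    set.seed(seed); sample(ylog, 5000)
  } else ylog
  shapiro_w <- if (length(sw_y) >= 3 && stats::sd(sw_y) > 0)
    unname(stats::shapiro.test(sw_y)$statistic) else NA_real_
  if (!is.na(shapiro_w) && shapiro_w < shapiro_warn_w)
    warning(sprintf(
      "log response departs from normality (Shapiro-Wilk W = %.3f); fitting anyway",
      shapiro_w))

  df <- table
  df$.ylog <- ylog
  for (v in factor_vars) df[[v]] <- factor(df[[v]])

  n <- nrow(df)
  if (is.null(split_fraction)) {
    train_idx <- seq_len(n)
    eval_idx <- seq_len(n)
  } else {
    stopifnot(split_fraction > 0, split_fraction <= 1)
    set.seed(seed)
    train_idx <- sort(sample(n, floor(split_fraction * n)))
    eval_idx <- if (split_fraction < 1) setdiff(seq_len(n), train_idx)
    else train_idx
  }

  fml <- stats::as.formula(paste(
    ".ylog ~",
    paste(c(sprintf("s(%s)", smooth_vars), factor_vars), collapse = " + ")))
  model <- mgcv::gam(fml, data = df[train_idx, , drop = FALSE],
                     method = "REML")
  res <- stats::residuals(model, type = "response")
  S <- smearing_factor(res)

  fit <- structure(
    list(model = model, smearing = S, residuals = res,
         resid_sd = stats::sd(res), shapiro_w = shapiro_w,
         smooth_vars = smooth_vars, factor_vars = factor_vars,
         response = response, train_idx = train_idx,
         factor_levels = lapply(
           stats::setNames(factor_vars, factor_vars),
           function(v) levels(df[[v]][train_idx, drop = TRUE]))),
    class = "olsen_fit")

  eval_df <- df[eval_idx, , drop = FALSE]
  pred <- predict_concentration(fit, eval_df)
  fit$metrics <- model_metrics(y_all[eval_idx], pred,
                               aic = stats::AIC(model))
  fit
}

#' Back-transformed, smearing-corrected concentration predictions
#'
#' `S * exp(yhat_log)`: the model's log-scale prediction exponentiated and
#' rescaled by the smearing factor; always strictly positive. Countries not
#' seen in training are routed to the `"other"` level (with a message) when
#' that level exists; unseen levels of any other factor are an error.
#'
#' @param fit an `olsen_fit`.
#' @param newdata data.frame with the model's covariates.
#' @return numeric vector of Olsen P predictions, mg kg^-1.
#' @export
predict_concentration <- function(fit, newdata) {
  stopifnot(inherits(fit, "olsen_fit"))
  for (v in fit$factor_vars) {
    lv <- fit$factor_levels[[v]]
    vals <- as.character(newdata[[v]])
    unseen <- !(vals %in% lv)
    if (any(unseen)) {
      if (v == "country" && "other" %in% lv) {
        message(sum(unseen), " record(s) from countries unseen in training",
                " routed to the \"other\" level")
        vals[unseen] <- "other"
      } else {
        stop("unseen level(s) in factor '", v, "': ",
             paste(unique(vals[unseen]), collapse = ", "))
      }
    }
    newdata[[v]] <- factor(vals, levels = lv)
  }
  yhat <- as.numeric(mgcv::predict.gam(fit$model, newdata = newdata))
  fit$smearing * exp(yhat)
}

#' @export
print.olsen_fit <- function(x, ...) {
  cat("<olsen_fit> log-scale additive model\n")
  cat(sprintf("  smooth terms : %s\n", paste(x$smooth_vars, collapse = ", ")))
  if (length(x$factor_vars))
    cat(sprintf("  factor terms : %s\n", paste(x$factor_vars, collapse = ", ")))
  cat(sprintf("  training rows: %d   residual SD (log): %.3f\n",
              length(x$train_idx), x$resid_sd))
  cat(sprintf("  smearing S   : %.4f   Shapiro-Wilk W: %.3f\n",
              x$smearing, x$shapiro_w))
  cat(sprintf("  R2: %.1f%%   NSE: %.3f   AIC: %.1f\n",
              x$metrics$r_squared, x$metrics$nse, x$metrics$aic))
  invisible(x)
}
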