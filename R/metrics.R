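#' Calibration figures of merit
#'
#' `SEC = sqrt(SSE / (n - n_factors - 1))` — the residual standard error
#' penalized for the latent factors — and `R2_CAL = 1 - SSE/SST`.
#'
#' @param y Reference values.
#' @param yhat Fitted values.
#' @param n_factors Number of PLS factors in the model.
#' @return List with `sec` and `r2_cal`.
#' @export
calibration_stats <- function(y, yhat, n_factors) {
  n <- length(y)
  if (n <= n_factors + 1)
    stop("need n > n_factors + 1 samples for SEC", call. = FALSE)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("zero-variance reference values", call. = FALSE)
  sse <- sum((yhat - y)^2)
  list(sec = sqrt(sse / (n - n_factors - 1)), r2_cal = 1 - sse / sst)
}

#' External validation report
#'
#' Conventional NIRS validation statistics: `bias = mean(yhat - y)`;
#' bias-corrected `SEP = sqrt(sum((yhat - y - bias)^2) / (n - 1))` (the
#' uncorrected RMSEP is also reported); the least-squares `slope` of the
#' reference regressed on the predicted values; `R2_VAL`, the squared
#' Pearson correlation; `RPD = sd(y) / SEP`; and
#' `RER = (max(y) - min(y)) / SEP`. When SEP is 0 the ratios are
#' reported as `Inf` with a warning.
#'
#' @param y Reference values of the validation samples.
#' @param yhat Predicted values.
#' @return A `validation_report` list: `n`, `r2_val`, `sep`, `rmsep`,
#'   `bias`, `slope`, `slope_pred_on_ref`, `rpd`, `rer`, `quality`.
#' @export
validation_stats <- function(y, yhat) {
  n <- length(y)
  if (n < 3) stop("need at least 3 validation samples", call. = FALSE)
  e <- yhat - y
  bias <- mean(e)
  sep <- sqrt(sum((e - bias)^2) / (n - 1))
  rmsep <- sqrt(mean(e^2))
  slope <- if (stats::var(yhat) > 0)
    stats::cov(y, yhat) / stats::var(yhat) else NA_real_
  slope_alt <- if (stats::var(y) > 0)
    stats::cov(y, yhat) / stats::var(y) else NA_real_
  r2 <- if (stats::var(yhat) > 0 && stats::var(y) > 0)
    stats::cor(y, yhat)^2 else NA_real_
  if (sep == 0) {
    warning("SEP is zero; RPD and RER reported as Inf")
    rpd <- rer <- Inf
  } else {
    rpd <- stats::sd(y) / sep
    rer <- (max(y) - min(y)) / sep
  }
  rep_ <- structure(
    list(n = n, r2_val = r2, sep = sep, rmsep = rmsep, bias = bias,
         slope = slope, slope_pred_on_ref = slope_alt, rpd = rpd,
         rer = rer),
    class = "validation_report")
  rep_$quality <- classify_model(rep_)
  rep_
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> n=%d R2=%.3f SEP=%.4g bias=%.4g slope=%.3f RPD=%.2f RER=%.2f [%s]\n",
    x$n, x$r2_val, x$sep, x$bias, x$slope, x$rpd, x$rer, x$quality))
  invisible(x)
}

#' Classify prediction-model quality from RPD and RER
#'
#' The conventional thresholds: RPD >= 3 together with RER >= 10 marks a
#' model fit for quantitative prediction; RPD in 2.0-2.5 still supports
#' acceptable quantitative predictions for specific compounds (the Saeys
#' rule), and 2.5-3.0 rough screening; below 2.0 the model is
#' unreliable.
#'
#' @param report A `validation_report`, or a list with finite `rpd` and
#'   `rer`.
#' @return One of `"quantitative"`, `"screening"`, `"acceptable"`,
#'   `"unreliable"`.
#' @export
#' @examples
#' classify_model(list(rpd = 3.2, rer = 12))   # quantitative
#' classify_model(list(rpd = 2.28, rer = 16.4))  # acceptable
#' classify_model(list(rpd = 1.19, rer = 6.62))  # unreliable
classify_model <- function(report) {
  rpd <- report$rpd; rer <- report$rer
  if (!is.finite(rpd) || !is.finite(rer)) return(NA_character_)
  if (rpd >= 3 && rer >= 10) "quantitative"
  else if (rpd >= 2.5) "screening"
  else if (rpd >= 2.0) "acceptable"
  else "unreliable"
}

#' Grid search over preprocessing recipes
#'
#' Runs the full calibration protocol for every scatter-correction x
#' math-treatment combination: split into calibration/validation, fit
#' the recipe on the calibration set, eliminate outliers, cross-validate
#' and select factors, then validate externally. Rows are ranked by
#' R2_CV (descending), then SECV (ascending), then factor count
#' (ascending).
#'
#' @param spectra A `spectra_set` (raw, before preprocessing).
#' @param y Response vector aligned to the spectra.
#' @param scatters Character vector of scatter corrections (default the
#'   four used with derivative treatments).
#' @param treatments Character vector of math treatment codes.
#' @param variant PLS variant.
#' @param split_fraction Calibration fraction (default 0.75).
#' @param split_strategy `"rank"` or `"random"`.
#' @param k CV folds.
#' @param max_factors Cap on latent factors.
#' @param seed Seed driving the split and fold shuffles.
#' @param outlier_passes,t_crit,h_crit,cap Outlier-elimination settings
#'   (see [eliminate_outliers()]); `outlier_passes = 0` disables it.
#' @return List: `table` (one ranked row per recipe with calibration,
#'   CV and validation statistics; failed recipes carry an `error`
#'   message), `models` (per-recipe fitted detail, in table order).
#' @export
grid_search <- function(spectra, y,
                        scatters = c("SNV", "D", "SNV+D", "MSC"),
                        treatments = c("1.4.4.1", "2.4.4.1",
                                       "1.5.5.1", "2.5.5.1"),
                        variant = "modified",
                        split_fraction = 0.75,
                        split_strategy = "rank",
                        k = 6, max_factors = 16, seed = 1,
                        outlier_passes = 2, t_crit = 2.5, h_crit = 10,
                        cap = 0.10) {
  validate_spectra_set(spectra)
  y <- as.numeric(y)
  stopifnot(length(y) == length(spectra$sample_ids))
  sp <- split_calibration_validation(y, split_fraction, seed = seed,
                                     strategy = split_strategy)
  combos <- expand.grid(scatter = scatters, treatment = treatments,
                        stringsAsFactors = FALSE)
  rows <- vector("list", nrow(combos))
  fits <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    res <- tryCatch(
      run_one_recipe(spectra, y, combos$scatter[i], combos$treatment[i],
                     sp, variant, k, max_factors, seed,
                     outlier_passes, t_crit, h_crit, cap),
      error = function(e) list(error = conditionMessage(e)))
    if (!is.null(res$error)) {
      rows[[i]] <- data.frame(
        recipe = paste0(combos$scatter[i], "/", combos$treatment[i]),
        scatter = combos$scatter[i], treatment = combos$treatment[i],
        n_cal = NA, n_val = NA, n_factors = NA, n_outliers = NA,
        r2_cal = NA, sec = NA, r2_cv = NA, secv = NA, r2_val = NA,
        sep = NA, bias = NA, slope = NA, rpd = NA, rer = NA,
        quality = NA, error = res$error)
    } else {
      rows[[i]] <- res$row
      fits[[i]] <- res$fit
    }
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$r2_cv, tab$secv, tab$n_factors, tab$recipe,
               na.last = TRUE)
  list(table = tab[ord, , drop = FALSE], models = fits[ord],
       split = sp, seed = seed)
}

run_one_recipe <- function(spectra, y, scatter, treatment, sp, variant,
                           k, max_factors, seed, outlier_passes,
                           t_crit, h_crit, cap) {
  rec <- fit_recipe(recipe(scatter, treatment), spectra[sp$calibration, ])
  prep <- apply_recipe(spectra, rec)
  Xc <- prep$absorbance[sp$calibration, , drop = FALSE]
  yc <- y[sp$calibration]
  Xv <- prep$absorbance[sp$validation, , drop = FALSE]
  yv <- y[sp$validation]
  if (outlier_passes > 0) {
    el <- eliminate_outliers(Xc, yc, variant = variant, k = k,
                             max_factors = max_factors, seed = seed,
                             passes = outlier_passes, t_crit = t_crit,
                             h_crit = h_crit, cap = cap)
    model <- el$model; cv <- el$cv; kept <- el$kept; olog <- el$log
  } else {
    cv <- cross_validate(Xc, yc, k = k, max_factors = max_factors,
                         variant = variant, seed = seed)
    model <- fit_pls1(Xc, yc, cv$n_factors, variant)
    kept <- seq_along(yc)
    olog <- NULL
  }
  vrep <- validation_stats(yv, predict(model, Xv))
  a <- model$n_factors
  row <- data.frame(
    recipe = paste0(scatter, "/", treatment),
    scatter = scatter, treatment = treatment,
    n_cal = length(kept), n_val = length(yv), n_factors = a,
    n_outliers = length(yc) - length(kept),
    r2_cal = model$r2_cal, sec = model$sec,
    r2_cv = cv$r2_cv[a], secv = cv$secv[a],
    r2_val = vrep$r2_val, sep = vrep$sep, bias = vrep$bias,
    slope = vrep$slope, rpd = vrep$rpd, rer = vrep$rer,
    quality = vrep$quality, error = NA_character_)
  list(row = row,
       fit = list(recipe = rec, model = model, cv = cv, kept = kept,
                  outlier_log = olog, validation = vrep))
}
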