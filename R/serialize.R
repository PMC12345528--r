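#' Save a fitted calibration to disk
#'
#' Writes two files: `<path>.json` with the scalars (variant, factor
#' count, recipe string, SEC/SECV/R-squared, CV settings, outlier log)
#' and `<path>_arrays.csv`, a long-format companion (`name,row,col,
#' value` at 17 significant digits) holding every numeric array —
#' centering vector, weights, loadings, scalings, coefficients, scores
#' and any MSC reference. [load_calibration_model()] reconstructs the
#' fit exactly.
#'
#' @param fit A fitted calibration as produced by [grid_search()]'s
#'   `models` entries, or a bare list with elements `model` (a
#'   `pls_model`), `recipe`, optional `cv` and `outlier_log`.
#' @param path Stem path (without extension).
#' @return `path`, invisibly.
#' @export
save_calibration_model <- function(fit, path) {
  if (inherits(fit, "pls_model")) fit <- list(model = fit)
  m <- fit$model
  rec <- fit$recipe
  scalars <- list(
    variant = m$variant, n_factors = m$n_factors,
    y_center = m$y_center, intercept = m$intercept,
    sec = m$sec, r2_cal = m$r2_cal,
    recipe = if (!is.null(rec)) format(rec) else NULL,
    detrend_order = if (!is.null(rec)) rec$detrend_order else NULL,
    cv = if (!is.null(fit$cv))
      fit$cv[c("secv", "r2_cv", "n_factors", "seed")] else NULL,
    outlier_log = if (!is.null(fit$outlier_log) && nrow(fit$outlier_log))
      as.data.frame(fit$outlier_log) else NULL)
  # scalars that must reload bit-exactly ride in the array file too
  # (JSON text serialization keeps ~15 significant digits)
  arrs <- list(x_center = m$x_center, W = m$W, P = m$P, q = m$q,
               x_scales = m$x_scales, y_scales = m$y_scales,
               coefficients = m$coefficients, scores = m$scores,
               fitted = m$fitted,
               scalar_exact = c(m$y_center, m$intercept, m$sec, m$r2_cal))
  if (!is.null(rec) && !is.null(rec$msc_reference))
    arrs$msc_reference <- rec$msc_reference
  scalars$array_dims <- lapply(arrs, function(a)
    if (is.matrix(a)) dim(a) else length(a))
  jsonlite::write_json(scalars, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  rows <- lapply(names(arrs), function(nm) {
    a <- arrs[[nm]]
    if (is.matrix(a)) {
      idx <- which(!is.na(a), arr.ind = TRUE)
      data.frame(name = nm, row = idx[, 1], col = idx[, 2],
                 value = sprintf("%.17g", a[idx]))
    } else {
      data.frame(name = nm, row = seq_along(a), col = 1L,
                 value = sprintf("%.17g", a))
    }
  })
  utils::write.csv(do.call(rbind, rows), paste0(path, "_arrays.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reload a saved calibration
#'
#' @param path The stem path given to [save_calibration_model()].
#' @return A list with `model` (a `pls_model`), `recipe` (or `NULL`),
#'   `cv` and `outlier_log`, numerically identical to what was saved.
#' @export
load_calibration_model <- function(path) {
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  long <- utils::read.csv(paste0(path, "_arrays.csv"),
                          colClasses = c("character", "integer",
                                         "integer", "numeric"))
  dims <- sc$array_dims
  grab <- function(nm) {
    d <- long[long$name == nm, ]
    if (!nrow(d)) return(NULL)
    dm <- dims[[nm]]
    if (length(dm) == 2) {
      m <- matrix(0, dm[1], dm[2])
      m[cbind(d$row, d$col)] <- d$value
      m
    } else {
      v <- numeric(dm)
      v[d$row] <- d$value
      v
    }
  }
  ex <- grab("scalar_exact")
  model <- structure(list(
    variant = sc$variant, n_factors = sc$n_factors,
    x_center = grab("x_center"), y_center = ex[1],
    W = grab("W"), P = grab("P"), q = grab("q"),
    x_scales = grab("x_scales"), y_scales = grab("y_scales"),
    scores = grab("scores"), intercept = ex[2],
    coefficients = grab("coefficients"), fitted = grab("fitted"),
    sec = ex[3], r2_cal = ex[4]), class = "pls_model")
  rec <- NULL
  if (!is.null(sc$recipe)) {
    rec <- recipe(sc$recipe)
    if (!is.null(sc$detrend_order)) rec$detrend_order <- sc$detrend_order
    msc_ref <- grab("msc_reference")
    if (!is.null(msc_ref)) rec$msc_reference <- msc_ref
  }
  list(model = model, recipe = rec, cv = sc$cv,
       outlier_log = sc$outlier_log)
}
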