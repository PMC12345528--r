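#' Chemical (t) outlier statistic
#'
#' The studentized residual of each sample against the calibration
#' standard error: `t_i = |yhat_i - y_i| / SEC`. Samples with
#' `t >= t_crit` (conventionally 2.5) show a high discrepancy between
#' predicted and reference values and are flagged as chemical outliers.
#'
#' @param residuals Numeric vector `yhat - y`.
#' @param sec Calibration standard error (> 0).
#' @return Numeric vector of t statistics.
#' @export
t_statistic <- function(residuals, sec) {
  if (!is.finite(sec) || sec <= 0) {
    if (all(residuals == 0)) return(rep(0, length(residuals)))
    stop("SEC must be > 0 when residuals are nonzero", call. = FALSE)
  }
  abs(residuals) / sec
}

#' Global H (GH) spectral outlier statistic
#'
#' The squared Mahalanobis distance of each sample's PLS score vector
#' from the score centroid, divided by the number of factors. Samples
#' with `GH >= h_crit` have markedly different spectra from the
#' calibration population.
#'
#' @param scores PLS score matrix (samples x factors).
#' @return Numeric vector of GH values.
#' @export
gh_statistic <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores); a <- ncol(scores)
  if (n < 2 || a < 1) stop("need >= 2 samples and >= 1 factor", call. = FALSE)
  ctr <- colMeans(scores)
  S <- stats::cov(scores)
  ok <- tryCatch({solve(S); TRUE}, error = function(e) FALSE)
  if (!ok) stop("singular score covariance: GH undefined", call. = FALSE)
  stats::mahalanobis(scores, ctr, S) / a
}

#' Two-pass chemical and spectral outlier elimination
#'
#' Mirrors the WinISI routine: fit a cross-validated calibration, flag
#' chemical outliers at `t >= t_crit` and spectral outliers at
#' `GH >= h_crit` jointly, remove them and refit, for up to `passes`
#' rounds, stopping early when nothing is flagged. Cumulative removals
#' are capped at `cap` of the starting sample count; when the flags
#' exceed the cap, the worst offenders by `max(t/t_crit, GH/h_crit)` are
#' removed first.
#'
#' @param X Preprocessed spectra matrix.
#' @param y Response vector.
#' @param variant PLS variant (see [fit_pls1()]).
#' @param k CV folds used to pick the factor count each pass.
#' @param max_factors Cap on latent factors.
#' @param seed Seed for the CV fold shuffle.
#' @param passes Maximum elimination passes (default 2).
#' @param t_crit Critical t value (default 2.5, inclusive).
#' @param h_crit Critical GH value (default 10, inclusive).
#' @param cap Maximum fraction of samples removable in total (default
#'   0.10).
#' @return List: `kept` (indices into the original rows), `log` (an
#'   `outlier_log` data.frame: pass, id, reason, statistic), `fraction
#'   removed`, and the final refit `model` and `cv`.
#' @export
eliminate_outliers <- function(X, y, variant = "modified", k = 6,
                               max_factors = 16, seed = 1, passes = 2,
                               t_crit = 2.5, h_crit = 10, cap = 0.10) {
  X <- as.matrix(X); y <- as.numeric(y)
  n0 <- nrow(X)
  kept <- seq_len(n0)
  budget <- floor(cap * n0)
  log_rows <- list()
  model <- NULL; cv <- NULL
  for (pass in seq_len(passes)) {
    cv <- cross_validate(X[kept, , drop = FALSE], y[kept], k = k,
                         max_factors = max_factors, variant = variant,
                         seed = seed)
    a <- cv$n_factors
    if (length(kept) < 2 * a + 2)
      stop("too few samples (", length(kept), ") to support ", a,
           " factors during outlier elimination", call. = FALSE)
    model <- fit_pls1(X[kept, , drop = FALSE], y[kept], a, variant)
    tstat <- t_statistic(model$fitted - y[kept], model$sec)
    gh <- gh_statistic(model$scores)
    sev <- pmax(tstat / t_crit, gh / h_crit)
    flagged <- which(tstat >= t_crit | gh >= h_crit)
    if (!length(flagged)) break
    room <- budget - (n0 - length(kept))
    if (room <= 0) break
    flagged <- flagged[order(-sev[flagged])]
    drop_local <- flagged[seq_len(min(room, length(flagged)))]
    min_left <- 2 * a
    if (length(kept) - length(drop_local) < min_left)
      stop("outlier removal would leave fewer than ", min_left,
           " samples for ", a, " factors", call. = FALSE)
    reason <- ifelse(tstat[drop_local] >= t_crit &
                       gh[drop_local] >= h_crit, "t+H",
                     ifelse(tstat[drop_local] >= t_crit, "t", "H"))
    log_rows[[pass]] <- data.frame(
      pass = pass, id = kept[drop_local], reason = reason,
      t = tstat[drop_local], gh = gh[drop_local])
    kept <- kept[-drop_local]
  }
  # final refit on the kept set
  cv <- cross_validate(X[kept, , drop = FALSE], y[kept], k = k,
                       max_factors = max_factors, variant = variant,
                       seed = seed)
  model <- fit_pls1(X[kept, , drop = FALSE], y[kept], cv$n_factors, variant)
  log_df <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(pass = integer(), id = integer(), reason = character(),
               t = numeric(), gh = numeric())
  class(log_df) <- c("outlier_log", "data.frame")
  list(kept = kept, log = log_df,
       fraction_removed = (n0 - length(kept)) / n0,
       model = model, cv = cv)
}
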