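#' Fit a PLS1 calibration (standard or modified)
#'
#' Mean-centered NIPALS PLS1 on a single response. The `"modified"`
#' variant (MPLS, the WinISI default) rescales the X-residual columns and
#' the y-residual by their standard deviations after each factor is
#' extracted, before extracting the next, which damps the influence of
#' high-variance spectral regions on later factors. With one factor the
#' two variants coincide.
#'
#' Because every step of the modified algorithm is affine in the input
#' spectrum, predictions still reduce to `intercept + X %*% coefficients`
#' in the original (preprocessed) spectral space; those coefficients are
#' extracted and stored on the model.
#'
#' @param X Preprocessed spectra matrix (samples x wavelengths).
#' @param y Numeric response, one value per row of `X`.
#' @param n_factors Number of latent factors to extract.
#' @param variant `"modified"` (default) or `"standard"`.
#' @return An object of class `pls_model`: per-factor weights `W`,
#'   loadings `P`, y-loadings `q`, residual scalings, training scores
#'   `scores`, `coefficients`, `intercept`, fitted values, `sec` and
#'   `r2_cal`.
#' @export
fit_pls1 <- function(X, y, n_factors, variant = c("modified", "standard")) {
  variant <- match.arg(variant)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) != nrow(X)", call. = FALSE)
  if (stats::sd(y) < 1e-14) stop("zero-variance response", call. = FALSE)
  a_max <- min(n - 1, p)
  if (n_factors < 1 || n_factors > a_max)
    stop("n_factors must be in [1, ", a_max, "]", call. = FALSE)

  x_center <- colMeans(X)
  y_center <- mean(y)
  Xr <- sweep(X, 2, x_center)
  yr <- y - y_center

  W <- P <- matrix(0, p, n_factors)
  q <- numeric(n_factors)
  Tm <- matrix(0, n, n_factors)
  x_scales <- matrix(1, p, n_factors)  # scaling applied AFTER factor k
  y_scales <- rep(1, n_factors)

  for (k in seq_len(n_factors)) {
    w <- drop(crossprod(Xr, yr))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14)
      stop("X residual orthogonal to y at factor ", k,
           "; reduce n_factors", call. = FALSE)
    w <- w / nw
    t_ <- drop(Xr %*% w)
    tt <- sum(t_^2)
    p_ <- drop(crossprod(Xr, t_)) / tt
    qk <- sum(yr * t_) / tt
    Xr <- Xr - tcrossprod(t_, p_)
    yr <- yr - t_ * qk
    W[, k] <- w; P[, k] <- p_; q[k] <- qk; Tm[, k] <- t_
    if (variant == "modified" && k < n_factors) {
      sx <- sqrt(colSums(Xr^2) / (n - 1))
      sx[sx < 1e-12] <- 1
      sy <- sqrt(sum(yr^2) / (n - 1))
      if (sy < 1e-12) sy <- 1
      Xr <- sweep(Xr, 2, sx, "/")
      yr <- yr / sy
      x_scales[, k] <- sx
      y_scales[k] <- sy
    }
  }

  model <- structure(
    list(variant = variant, n_factors = n_factors,
         x_center = x_center, y_center = y_center,
         W = W, P = P, q = q, x_scales = x_scales, y_scales = y_scales,
         scores = Tm),
    class = "pls_model")

  # the factor recursion is linear in x: recover explicit coefficients by
  # pushing the origin and the unit basis through it
  basis <- rbind(rep(0, p), diag(p))
  pred0 <- pls_forward(model, basis, center = FALSE)[, n_factors]
  model$intercept <- y_center + pred0[1] -
    drop(pls_forward(model, matrix(x_center, 1), center = FALSE)[, n_factors])
  model$coefficients <- pred0[-1] - pred0[1]

  fitted <- drop(model$intercept + X %*% model$coefficients)
  model$fitted <- fitted
  if (n > n_factors + 1) {
    cs <- calibration_stats(y, fitted, n_factors)
    model$sec <- cs$sec
    model$r2_cal <- cs$r2_cal
  } else {
    # saturated fit: SEC's denominator n - a - 1 vanishes
    model$sec <- NA_real_
    model$r2_cal <- 1 - sum((fitted - y)^2) / sum((y - mean(y))^2)
  }
  model
}

# run the per-factor prediction recursion; returns an n x a matrix of
# cumulative predictions (in centered-y units) after 1..a factors.
pls_forward <- function(model, Xnew, center = TRUE) {
  Xr <- as.matrix(Xnew)
  if (center) Xr <- sweep(Xr, 2, model$x_center)
  a <- model$n_factors
  out <- matrix(0, nrow(Xr), a)
  acc <- numeric(nrow(Xr))
  ycum <- 1
  for (k in seq_len(a)) {
    t_ <- drop(Xr %*% model$W[, k])
    acc <- acc + ycum * model$q[k] * t_
    out[, k] <- acc
    if (k < a) {
      Xr <- Xr - tcrossprod(t_, model$P[, k])
      if (model$variant == "modified") {
        Xr <- sweep(Xr, 2, model$x_scales[, k], "/")
        ycum <- ycum * model$y_scales[k]
      }
    }
  }
  out
}

#' Predict from a fitted PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Preprocessed spectra matrix on the model's grid (same
#'   recipe and wavelength set as the training spectra).
#' @param ... Ignored.
#' @return Numeric vector of predictions,
#'   `intercept + newdata %*% coefficients`.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$coefficients))
    stop("newdata has ", ncol(X), " wavelengths; model expects ",
         length(object$coefficients),
         " (grid/recipe mismatch)", call. = FALSE)
  drop(object$intercept + X %*% object$coefficients)
}

#' Project spectra onto a model's score space
#'
#' Scores of new spectra in the model's latent-factor space, used for the
#' global H (Mahalanobis) spectral outlier statistic.
#'
#' @param model A `pls_model`.
#' @param Xnew Preprocessed spectra matrix; defaults to returning the
#'   training scores.
#' @return Matrix (samples x n_factors) of scores.
#' @export
pls_scores <- function(model, Xnew = NULL) {
  if (is.null(Xnew)) return(model$scores)
  Xr <- sweep(as.matrix(Xnew), 2, model$x_center)
  a <- model$n_factors
  out <- matrix(0, nrow(Xr), a)
  for (k in seq_len(a)) {
    t_ <- drop(Xr %*% model$W[, k])
    out[, k] <- t_
    if (k < a) {
      Xr <- Xr - tcrossprod(t_, model$P[, k])
      if (model$variant == "modified")
        Xr <- sweep(Xr, 2, model$x_scales[, k], "/")
    }
  }
  out
}

#' K-fold cross-validation with parsimonious factor selection
#'
#' Samples are shuffled once with the given seed and cut into `k`
#' contiguous blocks. For each factor count up to `max_factors`, SECV is
#' the root mean squared cross-validated residual,
#' `sqrt(sum((yhat_cv - y)^2) / n)`. The selected factor count is the
#' smallest whose SECV is within `secv_slack` (default 2%) of the minimum
#' — the "fewest factors near the minimum" rule.
#'
#' @param X Preprocessed spectra matrix.
#' @param y Response vector.
#' @param k Number of folds (default 6).
#' @param max_factors Largest factor count to try; capped by fold size.
#' @param variant PLS variant, as in [fit_pls1()].
#' @param seed Integer seed for the fold shuffle.
#' @param secv_slack Multiplier on the minimum SECV defining "near the
#'   minimum" (default 1.02).
#' @return List: `secv` and `r2_cv` per factor count, `n_factors`
#'   (selected), `folds` (fold assignment per sample), `cv_pred`
#'   (cross-validated predictions at the selected factor count), `seed`.
#' @export
cross_validate <- function(X, y, k = 6, max_factors = 16,
                           variant = c("modified", "standard"),
                           seed = 1, secv_slack = 1.02) {
  variant <- match.arg(variant)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (k > n) stop("k = ", k, " folds exceeds n = ", n, " samples",
                  call. = FALSE)
  if (k < 2) stop("need at least 2 folds", call. = FALSE)
  perm <- withr_seed(seed, sample.int(n))
  # contiguous blocks over the shuffled order
  sizes <- diff(round(seq(0, n, length.out = k + 1)))
  fold_of <- integer(n)
  fold_of[perm] <- rep(seq_len(k), times = sizes)
  a_max <- min(max_factors, n - max(sizes) - 1, ncol(X))
  if (a_max < 1) stop("too few samples per fold for even one factor",
                      call. = FALSE)
  pred <- matrix(NA_real_, n, a_max)
  a_eff <- a_max
  for (f in seq_len(k)) {
    test <- which(fold_of == f)
    train <- setdiff(seq_len(n), test)
    # near-noiseless folds can exhaust the predictive rank before a_max;
    # back off to the largest extractable factor count
    a_try <- a_max
    m <- NULL
    while (is.null(m) && a_try >= 1) {
      m <- tryCatch(
        fit_pls1(X[train, , drop = FALSE], y[train], a_try, variant),
        error = function(e) NULL)
      if (is.null(m)) a_try <- a_try - 1
    }
    if (is.null(m)) stop("PLS fit failed in every fold", call. = FALSE)
    a_eff <- min(a_eff, a_try)
    pred[test, seq_len(a_try)] <- m$y_center +
      pls_forward(m, X[test, , drop = FALSE])
  }
  pred <- pred[, seq_len(a_eff), drop = FALSE]
  secv <- sqrt(colSums((pred - y)^2) / n)
  sst <- sum((y - mean(y))^2)
  r2_cv <- 1 - colSums((pred - y)^2) / sst
  sel <- which(secv <= secv_slack * min(secv))[1]
  list(secv = secv, r2_cv = r2_cv, n_factors = sel,
       folds = fold_of, cv_pred = pred[, sel], seed = seed)
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Split samples into calibration and validation sets
#'
#' The default rank-stratified strategy sorts samples by the analyte
#' value and sends every `round(1/(1-fraction))`-th rank (offset so the
#' extremes stay in calibration) to validation, preserving range
#' coverage; `"random"` draws the validation set with the seed.
#'
#' @param y Analyte values (used for stratification) or, for
#'   `strategy = "random"`, anything of the right length.
#' @param fraction Calibration fraction (default 0.75).
#' @param seed Seed for the random strategy.
#' @param strategy `"rank"` (default) or `"random"`.
#' @return List with integer index vectors `calibration` and
#'   `validation`; disjoint and exhaustive.
#' @export
split_calibration_validation <- function(y, fraction = 0.75, seed = 1,
                                         strategy = c("rank", "random")) {
  strategy <- match.arg(strategy)
  n <- length(y)
  if (n < 4) stop("need at least 4 samples to split", call. = FALSE)
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)", call. = FALSE)
  if (strategy == "random") {
    n_cal <- round(fraction * n)
    cal <- withr_seed(seed, sort(sample.int(n, n_cal)))
    val <- setdiff(seq_len(n), cal)
  } else {
    step <- max(2, round(1 / (1 - fraction)))
    ord <- order(y, seq_along(y))  # ties broken by position: deterministic
    take <- seq(ceiling((step + 1) / 2), n, by = step)
    val <- sort(ord[take])
    cal <- setdiff(seq_len(n), val)
  }
  list(calibration = cal, validation = val)
}
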