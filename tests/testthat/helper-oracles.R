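# Independent oracles used to cross-check the package's numerics.
# These deliberately use different algorithms / code paths than R/.

# minimum-norm least squares via SVD pseudoinverse
oracle_pinv_fit <- function(X, y) {
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  s <- svd(Xc)
  pos <- s$d > max(dim(Xc)) * .Machine$double.eps * s$d[1]
  b <- s$v[, pos, drop = FALSE] %*%
    ((crossprod(s$u[, pos, drop = FALSE], y - ym)) / s$d[pos])
  drop(ym + Xc %*% b)
}

# explicit covariance-inverse Mahalanobis distance
oracle_gh <- function(scores) {
  ctr <- colMeans(scores)
  Sinv <- solve(stats::cov(scores))
  d2 <- apply(scores, 1, function(r) {
    v <- r - ctr
    drop(t(v) %*% Sinv %*% v)
  })
  d2 / ncol(scores)
}

# polynomial fit-and-subtract via an independent lm() fit
oracle_detrend <- function(x, w, order = 2) {
  wc <- w - mean(w)  # centered to keep the basis well conditioned
  unname(stats::resid(stats::lm(x ~ wc + I(wc^2))))
}

# per-spectrum scalar-regression MSC
oracle_msc_one <- function(x, ref) {
  fit <- stats::lm(x ~ ref)
  (x - coef(fit)[1]) / coef(fit)[2]
}

# brute-force gaussian band summation (independent of band_profile)
oracle_band_sum <- function(w, bands) {
  out <- rep(0, length(w))
  for (i in seq_len(nrow(bands))) {
    for (j in seq_along(w)) {
      z <- (w[j] - bands$center[i]) / bands$width[i]
      out[j] <- out[j] + bands$height[i] * exp(-z * z / 2)
    }
  }
  out
}

rbind_spectra <- function(a, b) {
  spectra_set(make.unique(c(a$sample_ids, b$sample_ids)),
              a$wavelengths, rbind(a$absorbance, b$absorbance))
}

# small random spectra fixture
random_spectra <- function(n = 8, p = 40, seed = 42,
                           wavelengths = seq(1100, by = 2,
                                             length.out = p)) {
  set.seed(seed)
  A <- matrix(rnorm(n * p, mean = 0.8, sd = 0.15), n, p)
  spectra_set(sprintf("X%02d", seq_len(n)), wavelengths, A)
}
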