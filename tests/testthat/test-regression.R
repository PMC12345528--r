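test_that("rank-1 noiseless data is fit exactly with one factor", {
  set.seed(2)
  y <- rnorm(10, 5, 2)
  s <- rnorm(30)
  X <- outer(y, s)
  for (v in c("standard", "modified")) {
    m <- fit_pls1(X, y, 1, v)
    expect_lt(max(abs(m$fitted - y)), 1e-8)
  }
})

test_that("full-rank PLS equals the pseudoinverse least-squares fit", {
  set.seed(4)
  r <- 4
  U <- qr.Q(qr(matrix(rnorm(12 * r), 12)))
  V <- qr.Q(qr(matrix(rnorm(6 * r), 6)))
  X <- U %*% diag(c(3, 2, 1.5, 1)) %*% t(V)  # exact rank 4
  y <- rnorm(12)
  m <- fit_pls1(X, y, r, "standard")
  expect_equal(m$fitted, oracle_pinv_fit(X, y), tolerance = 1e-8)
})

test_that("standard PLS1 matches the mixOmics NIPALS reference", {
  set.seed(6)
  n <- 25; p <- 30
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("w", 1:p)))
  y <- drop(X[, 1:5] %*% runif(5)) + rnorm(n, 0, 0.3)
  for (a in c(1, 3, 6)) {
    m <- fit_pls1(X, y, a, "standard")
    ref <- mixOmics::pls(X, y, ncomp = a, mode = "regression",
                         scale = FALSE)
    expect_equal(m$fitted,
                 unname(predict(ref, X)$predict[, 1, a]),
                 tolerance = 1e-8)
  }
})

test_that("prediction is the stored affine map and behaves linearly", {
  set.seed(8)
  X <- matrix(rnorm(20 * 15), 20)
  y <- rnorm(20)
  m <- fit_pls1(X, y, 4, "modified")
  # training predictions reproduce fitted values and the stored SEC
  expect_equal(predict(m, X), m$fitted, tolerance = 1e-12)
  expect_equal(sqrt(sum((m$fitted - y)^2) / (20 - 4 - 1)), m$sec)
  # duplicate row -> duplicate prediction
  expect_equal(predict(m, X[c(3, 3), ])[1], predict(m, X[c(3, 3), ])[2])
  # affine in the spectrum
  al <- 0.3
  mix <- al * X[1, ] + (1 - al) * X[2, ]
  pr <- unname(predict(m, rbind(X[1, ], X[2, ], mix)))
  expect_equal(pr[3], al * pr[1] + (1 - al) * pr[2], tolerance = 1e-10)
  expect_error(predict(m, X[, 1:10]), "mismatch")
})

test_that("modified and standard variants coincide at one factor", {
  set.seed(9)
  X <- matrix(rnorm(18 * 12), 18)
  y <- rnorm(18)
  m1 <- fit_pls1(X, y, 1, "modified")
  m2 <- fit_pls1(X, y, 1, "standard")
  expect_equal(m1$fitted, m2$fitted, tolerance = 1e-8)
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-8)
})

test_that("predictions are invariant to consistent wavelength permutation", {
  set.seed(10)
  X <- matrix(rnorm(20 * 15), 20)
  y <- rnorm(20)
  Xt <- matrix(rnorm(5 * 15), 5)
  perm <- sample(15)
  for (v in c("standard", "modified")) {
    p1 <- predict(fit_pls1(X, y, 3, v), Xt)
    p2 <- predict(fit_pls1(X[, perm], y, 3, v), Xt[, perm])
    expect_equal(p1, p2, tolerance = 1e-10)
  }
})

test_that("zero-variance y and excessive factor counts error", {
  X <- matrix(rnorm(20), 5)
  expect_error(fit_pls1(X, rep(2, 5), 1), "zero-variance")
  expect_error(fit_pls1(X, rnorm(5), 5), "n_factors")
})

test_that("cross-validation selects parsimoniously and is deterministic", {
  set.seed(12)
  n <- 30; p <- 20; r <- 3
  # noiseless latent-variable system: y is exactly linear in a rank-3 X
  Tm <- matrix(rnorm(n * r), n, r)
  X <- Tm %*% matrix(rnorm(r * p), r, p)
  y <- drop(Tm %*% c(1, -0.5, 2))
  cv <- cross_validate(X, y, k = 6, max_factors = 8, seed = 3)
  expect_lte(cv$secv[cv$n_factors], 1e-6)
  expect_true(all(cv$secv >= 0))
  expect_lte(cv$secv[cv$n_factors], cv$secv[1])
  cv2 <- cross_validate(X, y, k = 6, max_factors = 8, seed = 3)
  expect_identical(cv$folds, cv2$folds)
  expect_equal(cv$secv, cv2$secv)
  expect_error(cross_validate(X, y, k = 31), "exceeds")
})

test_that("leave-one-out SECV matches an explicit refit loop", {
  set.seed(13)
  n <- 14; p <- 10
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X[, 1:3] %*% c(1, -2, 0.5)) + rnorm(n, 0, 0.2)
  a <- 3
  cv <- cross_validate(X, y, k = n, max_factors = a, seed = 5)
  loo <- vapply(seq_len(n), function(i) {
    m <- fit_pls1(X[-i, ], y[-i], a, "modified")
    predict(m, X[i, , drop = FALSE])
  }, numeric(1))
  expect_equal(cv$secv[a], sqrt(mean((loo - y)^2)), tolerance = 1e-10)
})

test_that("calibration/validation splits are disjoint and range-covering", {
  set.seed(14)
  y <- rnorm(192)
  sp <- split_calibration_validation(y, 0.75)
  expect_equal(length(sp$calibration), 144)
  expect_equal(length(sp$validation), 48)
  expect_equal(sort(c(sp$calibration, sp$validation)), 1:192)
  expect_length(intersect(sp$calibration, sp$validation), 0)
  # stratified: validation extremes within calibration range
  expect_gte(min(y[sp$validation]), min(y[sp$calibration]))
  expect_lte(max(y[sp$validation]), max(y[sp$calibration]))
  # random strategy is seeded and exhaustive
  sr1 <- split_calibration_validation(y, 0.75, seed = 2, strategy = "random")
  sr2 <- split_calibration_validation(y, 0.75, seed = 2, strategy = "random")
  expect_identical(sr1, sr2)
  expect_equal(sort(c(sr1$calibration, sr1$validation)), 1:192)
  expect_error(split_calibration_validation(rnorm(3)), "at least 4")
})

test_that("saved models reload with identical numbers", {
  set.seed(15)
  s <- random_spectra(n = 12, p = 40)
  y <- rowMeans(s$absorbance[, 1:5]) + rnorm(12, 0, 0.01)
  rec <- fit_recipe(recipe("MSC", "1.4.4.1"), s)
  prep <- apply_recipe(s, rec)
  cv <- cross_validate(prep$absorbance, y, k = 4, max_factors = 3, seed = 1)
  model <- fit_pls1(prep$absorbance, y, cv$n_factors, "modified")
  stem <- withr::local_tempfile()
  save_calibration_model(list(model = model, recipe = rec, cv = cv), stem)
  back <- load_calibration_model(stem)
  expect_identical(back$model$coefficients, model$coefficients)
  expect_identical(back$model$W, unname(model$W))
  expect_identical(back$model$intercept, model$intercept)
  expect_identical(back$recipe$msc_reference, unname(rec$msc_reference))
  expect_equal(predict(back$model, prep$absorbance), model$fitted,
               tolerance = 0)
})
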