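test_that("calibration statistics follow their defining formulas", {
  y <- c(1, 2, 3, 4, 5, 6)
  cs <- calibration_stats(y, y, 2)
  expect_equal(cs$sec, 0); expect_equal(cs$r2_cal, 1)
  cs0 <- calibration_stats(y, rep(mean(y), 6), 2)
  expect_equal(cs0$r2_cal, 0)
  set.seed(30)
  yh <- y + rnorm(6, 0, 0.4)
  cs2 <- calibration_stats(y, yh, 2)
  expect_equal(cs2$sec, sqrt(sum((yh - y)^2) / (6 - 2 - 1)))
  expect_equal(cs2$r2_cal, 1 - sum((yh - y)^2) / sum((y - mean(y))^2))
  expect_error(calibration_stats(y[1:3], y[1:3], 2), "n >")
  expect_error(calibration_stats(rep(1, 6), rep(1, 6), 2), "zero-variance")
})

test_that("validation statistics follow the conventional NIRS definitions", {
  y <- c(2, 4, 6, 8, 10)
  # perfect prediction: SEP is 0, so the Inf-ratio warning is expected
  v <- suppressWarnings(validation_stats(y, y))
  expect_equal(v$bias, 0); expect_equal(v$slope, 1)
  expect_equal(v$r2_val, 1)
  expect_equal(v$sep, 0)
  # constant offset: all error goes to bias, none to (bias-corrected) SEP
  expect_warning(v2 <- validation_stats(y, y + 3), "SEP is zero")
  expect_equal(v2$bias, 3)
  expect_equal(v2$sep, 0)
  expect_equal(v2$slope, 1)
  expect_true(is.infinite(v2$rpd) && is.infinite(v2$rer))
  # ratio definitions: RPD = sd/SEP, RER = range/SEP
  set.seed(31)
  yy <- rnorm(40, 10, 2.4)
  vv <- validation_stats(yy, yy + rnorm(40, 0, 1))
  expect_equal(vv$rpd, sd(yy) / vv$sep)
  expect_equal(vv$rer, diff(range(yy)) / vv$sep)
  expect_equal(vv$rer / vv$rpd, diff(range(yy)) / sd(yy))
  expect_error(validation_stats(1:2, 1:2), "at least 3")
})

test_that("R2_VAL is affine-invariant in predictions while SEP is not", {
  set.seed(32)
  y <- rnorm(30, 5, 1)
  yh <- y + rnorm(30, 0, 0.3)
  a <- validation_stats(y, yh)
  b <- suppressWarnings(validation_stats(y, 2 + 3 * yh))
  expect_equal(a$r2_val, b$r2_val, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(a$sep, b$sep)))
})

test_that("quality classes reproduce the conventional RPD/RER judgments", {
  expect_equal(classify_model(list(rpd = 3.2, rer = 12)), "quantitative")
  expect_equal(classify_model(list(rpd = 2.28, rer = 16.40)), "acceptable")
  expect_equal(classify_model(list(rpd = 2.7, rer = 11)), "screening")
  expect_equal(classify_model(list(rpd = 1.19, rer = 6.62)), "unreliable")
  # RPD >= 3 alone is not enough without adequate RER
  expect_false(classify_model(list(rpd = 3.5, rer = 8)) == "quantitative")
  expect_true(is.na(classify_model(list(rpd = Inf, rer = Inf))))
})

test_that("grid search covers the recipe grid and ranks deterministically", {
  cfg <- synthetic_config(n = 36, noise_sd = 5e-4, seed = 33,
                          wavelengths = seq(1100, 2498, by = 8))
  sim <- simulate_excreta_dataset(cfg)
  gs <- grid_search(sim$spectra, sim$reference$Ti_g_kg,
                    scatters = c("SNV", "MSC"),
                    treatments = c("1.4.4.1", "2.4.4.1"),
                    k = 4, max_factors = 6, seed = 2,
                    outlier_passes = 0)
  expect_equal(nrow(gs$table), 4)
  expect_setequal(gs$table$recipe,
                  c("SNV/1.4.4.1", "SNV/2.4.4.1",
                    "MSC/1.4.4.1", "MSC/2.4.4.1"))
  # ranked by R2_CV then SECV
  expect_true(all(diff(gs$table$r2_cv) <= 1e-12))
  gs2 <- grid_search(sim$spectra, sim$reference$Ti_g_kg,
                     scatters = c("SNV", "MSC"),
                     treatments = c("1.4.4.1", "2.4.4.1"),
                     k = 4, max_factors = 6, seed = 2,
                     outlier_passes = 0)
  expect_identical(gs$table, gs2$table)
  # with the optional "none" scatter the grid grows accordingly
  gs3 <- grid_search(sim$spectra, sim$reference$Ti_g_kg,
                     scatters = c("none", "SNV"),
                     treatments = "1.4.4.1",
                     k = 4, max_factors = 4, seed = 2,
                     outlier_passes = 0)
  expect_equal(nrow(gs3$table), 2)
})

test_that("a failing recipe yields an error row, not a crash", {
  s <- random_spectra(n = 12, p = 15)
  y <- rnorm(12)
  # treatment window longer than the 15-point grid must fail per-recipe
  gs <- grid_search(s, y, scatters = "SNV",
                    treatments = c("1.4.4.1", "2.20.1.1"),
                    k = 3, max_factors = 2, seed = 1, outlier_passes = 0)
  expect_equal(sum(!is.na(gs$table$error)), 1)
  expect_match(gs$table$error[!is.na(gs$table$error)], "too short")
})
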