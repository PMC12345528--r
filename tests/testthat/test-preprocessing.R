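test_that("SNV centers and scales each spectrum", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(1)
  A <- matrix(rnorm(200, 1, 0.3), 5)
  S <- snv(A)
  expect_equal(unname(rowMeans(S)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(S, 1, sd)), rep(1, 5), tolerance = 1e-12)
  # idempotence
  expect_equal(snv(S), S, tolerance = 1e-10)
  expect_error(snv(c(5, 5, 5)), "degenerate")
})

test_that("detrend removes its polynomial and matches the oracle", {
  w <- seq(1100, 1298, by = 2)
  quad <- 2 + 0.01 * w - 3e-6 * w^2
  expect_lt(max(abs(detrend(quad, w, 2))), 1e-10)
  set.seed(7)
  x <- rnorm(length(w))
  d <- detrend(x, w, 2)
  # orthogonal to the polynomial basis (cosine of angle ~ 0)
  B <- cbind(1, w, w^2)
  cosang <- abs(crossprod(B, d)) /
    (sqrt(colSums(B^2)) * sqrt(sum(d^2)))
  expect_lt(max(cosang), 1e-10)
  expect_equal(d, oracle_detrend(x, w, 2), tolerance = 1e-8)
  expect_error(detrend(c(1, 2, 3), c(1100, 1102, 1104), order = 2),
               "order\\+1")
})

test_that("MSC inverts affine scatter against the stored reference", {
  set.seed(11)
  ref <- rnorm(50, 1, 0.2)
  expect_equal(msc(3 + 2 * ref, ref), ref, tolerance = 1e-10)
  expect_equal(msc(ref, ref), ref, tolerance = 1e-12)
  A <- matrix(rnorm(250, 1, 0.2), 5)
  batch <- msc(A, ref)
  for (i in 1:5)
    expect_equal(unname(batch[i, ]), unname(oracle_msc_one(A[i, ], ref)),
                 tolerance = 1e-10)
  expect_error(msc(rep(0, 50), ref), "slope")
})

test_that("gap-segment derivatives match their analytic forms", {
  w <- seq(1100, by = 2, length.out = 60)
  i <- seq_along(w)
  # constant spectrum: any derivative is zero
  for (tr in c("1.4.4.1", "2.5.5.1"))
    expect_equal(max(abs(gap_segment_derivative(
      matrix(1, 1, 60), w, tr)$absorbance)), 0)
  # linear ramp, d=1, s1=s2=1: constant m*g
  m <- 0.03
  for (g in c(2, 4, 5)) {
    d <- gap_segment_derivative(matrix(m * i, 1), w,
                                paste0("1.", g, ".1.1"))
    expect_equal(unname(d$absorbance[1, ]),
                 rep(m * g, ncol(d$absorbance)), tolerance = 1e-12)
  }
  # quadratic, d=2, s1=s2=1: constant 2*g^2
  for (g in c(3, 5)) {
    d <- gap_segment_derivative(matrix(as.numeric(i^2), 1), w,
                                paste0("2.", g, ".1.1"))
    expect_equal(unname(d$absorbance[1, ]),
                 rep(2 * g^2, ncol(d$absorbance)), tolerance = 1e-10)
  }
  # grid shortens, never pads
  d <- gap_segment_derivative(matrix(rnorm(60), 1), w, "2.4.4.1")
  expect_lt(length(d$wavelengths), 60)
  expect_true(all(d$wavelengths %in% w))
  expect_error(gap_segment_derivative(matrix(1, 1, 5), w[1:5], "2.4.4.1"),
               "too short")
})

test_that("gap-segment derivative is linear in the spectra", {
  set.seed(5)
  w <- seq(1100, by = 2, length.out = 80)
  x <- matrix(rnorm(80), 1); y <- matrix(rnorm(80), 1)
  for (tr in c("1.4.4.1", "2.5.5.1", "0.1.3.3")) {
    lhs <- gap_segment_derivative(2.5 * x - 1.2 * y, w, tr)$absorbance
    rhs <- 2.5 * gap_segment_derivative(x, w, tr)$absorbance -
      1.2 * gap_segment_derivative(y, w, tr)$absorbance
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("math treatment codes parse and round-trip", {
  tr <- math_treatment("1.4.4.1")
  expect_equal(format(tr), "1.4.4.1")
  expect_equal(tr$d, 1); expect_equal(tr$g, 4)
  expect_error(math_treatment("3.4.4.1"), "derivative order")
  expect_error(math_treatment("1.0.4.1"), ">= 1")
  expect_error(math_treatment("1.4.4"), "four")
})

test_that("recipes compose scatter then derivative and honor MSC contract", {
  s <- random_spectra(n = 6, p = 50)
  # identity recipe
  id <- apply_recipe(s, recipe("none", "0.1.1.1"))
  expect_equal(id$absorbance, s$absorbance)
  # composition: SNV recipe on a batch == per-spectrum snv then derivative
  rec <- recipe("SNV", "1.4.4.1")
  full <- apply_recipe(s, rec)
  for (i in c(1, 4)) {
    one <- gap_segment_derivative(
      matrix(snv(s$absorbance[i, ]), 1), s$wavelengths, "1.4.4.1")
    expect_equal(unname(full$absorbance[i, ]),
                 unname(one$absorbance[1, ]), tolerance = 1e-12)
  }
  # recipe string parsing round-trips
  expect_equal(format(recipe("SNV+D/2.4.4.1")), "SNV+D/2.4.4.1")
  # MSC reference fixed at fit time and reused for new spectra
  cal <- s[1:4, ]; val <- s[5:6, ]
  mrec <- fit_recipe(recipe("MSC", "0.1.1.1"), cal)
  expect_equal(mrec$msc_reference, colMeans(cal$absorbance))
  v1 <- apply_recipe(val, mrec)
  expect_equal(v1$absorbance,
               msc(val$absorbance, colMeans(cal$absorbance)),
               ignore_attr = TRUE)
  expect_error(apply_recipe(val, recipe("MSC", "0.1.1.1")),
               "fitted")
})

test_that("corrections are invariant to sample order and extra samples", {
  s <- random_spectra(n = 6, p = 50)
  perm <- c(4, 2, 6, 1, 3, 5)
  for (rc in list(recipe("SNV", "1.4.4.1"), recipe("D", "2.4.4.1"),
                  recipe("SNV+D", "1.5.5.1"))) {
    a <- apply_recipe(s, rc)$absorbance
    b <- apply_recipe(s[perm, ], rc)$absorbance
    expect_equal(unname(b), unname(a[perm, ]), tolerance = 1e-12)
    # adding unrelated samples changes nothing for the originals
    extra <- apply_recipe(rbind_spectra(s, random_spectra(2, 50, seed = 9)),
                          rc)$absorbance
    expect_equal(unname(extra[1:6, ]), unname(a), tolerance = 1e-12)
  }
  # MSC's invariance takes the fixed-reference form instead
  mrec <- fit_recipe(recipe("MSC", "1.4.4.1"), s)
  a <- apply_recipe(s, mrec)$absorbance
  b <- apply_recipe(s[perm, ], mrec)$absorbance
  expect_equal(unname(b), unname(a[perm, ]), tolerance = 1e-12)
})
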