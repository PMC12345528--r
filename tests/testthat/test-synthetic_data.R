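test_that("marker mass balance is exact in the reference table", {
  diet <- diet_spec()
  sim <- simulate_excreta_dataset(synthetic_config(n = 50, seed = 40), diet)
  r <- sim$reference
  expect_equal(diet$ti_pct / (1 - r$DMD), r$Ti_g_kg / 10, tolerance = 1e-14)
  expect_equal(diet$yb_pct / (1 - r$DMD), r$Yb_g_kg / 10, tolerance = 1e-14)
  expect_equal(diet$peg_pct / (1 - r$DMD), r$PEG_pct, tolerance = 1e-14)
  # formula inversion example: DMD 0.75 at diet Ti 1.2 g/kg -> 4.8 g/kg
  expect_equal(1.2 / (1 - 0.75), 4.8)
})

test_that("the generator is fully determined by its seed", {
  a <- simulate_excreta_dataset(synthetic_config(n = 30, seed = 41))
  b <- simulate_excreta_dataset(synthetic_config(n = 30, seed = 41))
  expect_identical(a$spectra$absorbance, b$spectra$absorbance)
  expect_identical(a$reference, b$reference)
  c_ <- simulate_excreta_dataset(synthetic_config(n = 30, seed = 42))
  expect_false(identical(a$spectra$absorbance, c_$spectra$absorbance))
  # the generator leaves the global RNG stream untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulate_excreta_dataset(
    synthetic_config(n = 5, seed = 7)))
  expect_identical(rnorm(1), before)
})

test_that("noise- and scatter-free spectra equal the Beer-Lambert sum", {
  cfg <- synthetic_config(n = 4, noise_sd = 0, scatter = FALSE, seed = 43)
  diet <- diet_spec()
  sim <- simulate_excreta_dataset(cfg, diet)
  comp <- attr(sim, "composition")
  r <- sim$reference
  w <- cfg$wavelengths
  for (i in 1:4) {
    expected <- rep(0, length(w))
    for (nm in colnames(comp))
      expected <- expected +
        comp[i, nm] * oracle_band_sum(w, cfg$component_bands[[nm]])
    expected <- expected +
      (r$PEG_pct[i] / 100) * oracle_band_sum(w, cfg$peg_bands) +
      r$Yb_g_kg[i] * oracle_band_sum(w, cfg$marker_bands$Yb) +
      r$Ti_g_kg[i] * oracle_band_sum(w, cfg$marker_bands$Ti)
    expect_equal(unname(sim$spectra$absorbance[i, ]), expected,
                 tolerance = 1e-12)
  }
})

test_that("marker concentration dispersion propagates from the DMD spread", {
  cfg <- synthetic_config(n = 400, seed = 44)
  sim <- simulate_excreta_dataset(cfg)
  cv_ti <- 100 * sd(sim$reference$Ti_g_kg) / mean(sim$reference$Ti_g_kg)
  # delta method: CV ~ dmd_sd / (1 - dmd_mean) = 11.5% at the defaults
  expect_gt(cv_ti, 8)
  expect_lt(cv_ti, 15)
  expect_equal(mean(sim$reference$DMD), 0.74, tolerance = 0.01)
})

test_that("the PEG spiking design realizes the fortified-sample plan", {
  cfg <- synthetic_config(noise_sd = 2e-4, seed = 45)
  sp <- spike_peg_design(cfg)
  expect_equal(length(sp$spectra$sample_ids), 27)
  expect_equal(sort(unique(sp$reference$PEG_pct)), 0:15)
  expect_equal(sum(sp$reference$PEG_pct %in% 0:10), 22)  # duplicated levels
  # configurable plan: level set {0, 15} spans the reference extremes
  sp2 <- spike_peg_design(cfg, levels = c(0, 15),
                          replicate_levels = integer())
  expect_equal(range(sp2$reference$PEG_pct), c(0, 15))
  expect_error(spike_peg_design(cfg, levels = c(0, 100)), "\\[0, 100\\)")
})

test_that("an unspiked, artifact-free sample reproduces the base spectrum", {
  cfg <- synthetic_config(noise_sd = 0, scatter = FALSE, seed = 46)
  base <- sin(seq(0, 3, length.out = length(cfg$wavelengths))) + 1
  sp <- spike_peg_design(cfg, base = base, levels = c(0, 5),
                         replicate_levels = integer())
  expect_equal(unname(sp$spectra$absorbance[1, ]), base)
  # and a spiked one is the exact mass-fraction mixture
  pegp <- band_profile(cfg$wavelengths, cfg$peg_bands)
  expect_equal(unname(sp$spectra$absorbance[2, ]),
               0.95 * base + 0.05 * pegp, tolerance = 1e-14)
})

test_that("noise- and scatter-free spiked spectra determine PEG exactly", {
  cfg <- synthetic_config(noise_sd = 0, scatter = FALSE, seed = 47)
  sp <- spike_peg_design(cfg)
  # full-rank linear regression on a handful of wavelengths recovers the
  # mass fraction exactly (oracle equivalence with the mixing model)
  X <- sp$spectra$absorbance[, c(100, 250, 320, 400, 550)]
  fit <- lm(sp$reference$PEG_pct ~ X)
  expect_lt(max(abs(resid(fit))), 1e-9)
})
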