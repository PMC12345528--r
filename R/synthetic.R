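#' Marker dosing of the experimental diets
#'
#' Inclusion rates of the three external markers on an as-fed basis,
#' dosed as the compounds actually mixed into feed: titanium dioxide,
#' ytterbium oxide and polyethylene glycol.
#'
#' @param tio2_g_kg TiO2 inclusion, g/kg as fed (default 2).
#' @param yb2o3_mg_kg Yb2O3 inclusion, mg/kg as fed (default 50).
#' @param peg_g_kg PEG inclusion, g/kg as fed (default 5).
#' @param report_as `"element"` (default) or `"oxide"`: the basis on
#'   which marker concentrations are carried through mass balance.
#' @return A `diet_spec` object with diet marker concentrations
#'   converted to `% of DM` on the requested basis (`ti_pct`, `yb_pct`,
#'   `peg_pct`).
#' @export
diet_spec <- function(tio2_g_kg = 2, yb2o3_mg_kg = 50, peg_g_kg = 5,
                      report_as = c("element", "oxide")) {
  report_as <- match.arg(report_as)
  if (tio2_g_kg <= 0 || yb2o3_mg_kg <= 0 || peg_g_kg <= 0)
    stop("marker inclusion rates must be > 0", call. = FALSE)
  ti <- if (report_as == "element")
    oxide_to_element(tio2_g_kg, "TiO2") else tio2_g_kg
  yb <- if (report_as == "element")
    oxide_to_element(yb2o3_mg_kg / 1000, "Yb2O3") else yb2o3_mg_kg / 1000
  structure(list(
    tio2_g_kg = tio2_g_kg, yb2o3_mg_kg = yb2o3_mg_kg,
    peg_g_kg = peg_g_kg, report_as = report_as,
    ti_pct = ti / 10,   # g/kg -> % of mass
    yb_pct = yb / 10,
    peg_pct = peg_g_kg / 10), class = "diet_spec")
}

# default synthetic band sets (all synthetic stand-ins, centred near
# standard NIR assignments): gaussian bands (center nm, sd nm, height)
default_component_bands <- function() {
  band <- function(...) data.frame(...)
  list(
    protein = band(center = c(2055, 2180, 1510), width = c(40, 35, 30),
                   height = c(0.55, 0.50, 0.25)),
    carbohydrate = band(center = c(1200, 1580, 2100, 2280),
                        width = c(45, 50, 40, 35),
                        height = c(0.30, 0.35, 0.60, 0.45)),
    lipid = band(center = c(1725, 2310), width = c(25, 30),
                 height = c(0.45, 0.40)),
    water = band(center = c(1450, 1940), width = c(45, 55),
                 height = c(0.50, 0.70)),
    baseline = band(center = 1800, width = 2000, height = 0.60))
}

default_peg_bands <- function()
  data.frame(center = c(1734, 2245, 2320), width = c(20, 28, 22),
             height = c(0.90, 0.80, 0.60))

default_marker_bands <- function()
  list(
    # organo-complex signatures (heights are per unit g/kg of element)
    Yb = data.frame(center = c(1680, 2332), width = c(18, 20),
                    height = c(0.45, 0.30)),
    Ti = data.frame(center = c(1915, 2205), width = c(22, 24),
                    height = c(0.018, 0.014)))

#' Configuration of the synthetic excreta-spectra generator
#'
#' Spectra are Beer-Lambert mixtures of synthetic organic component
#' profiles (gaussian band sets for protein, carbohydrate, lipid,
#' residual water and a broad baseline), a pure-PEG profile, and
#' marker-associated organo-complex signatures whose amplitude scales
#' with the marker concentration (minerals absorb through their organic
#' complexes, not directly). Each sample is then warped by an affine
#' scatter artifact (multiplicative gain, additive offset, linear tilt)
#' and white absorbance noise is added last, mirroring the physical
#' measurement order.
#'
#' @param n Number of samples (default 192, the study's excreta count).
#' @param wavelengths Grid in nm (default 1100-2498 at 2 nm, 700
#'   points).
#' @param dmd_mean,dmd_sd Dry-matter digestibility distribution
#'   (truncated normal; defaults 0.74 and 0.03).
#' @param dmd_range Truncation interval for DMD draws (default
#'   `c(0, 0.95)`).
#' @param composition_cv Lognormal coefficient of variation of the
#'   organic component mass fractions across samples (default 0.10).
#' @param component_bands,peg_bands,marker_bands Band definitions
#'   (center, width, height data.frames); see defaults.
#' @param scatter Logical: apply gain/offset/tilt artifacts (default
#'   `TRUE`).
#' @param gain_range,offset_range,tilt_range Uniform ranges of the
#'   scatter artifact parameters.
#' @param noise_sd Additive absorbance noise standard deviation
#'   (default 5e-4, typical instrument noise).
#' @param seed Integer seed; fully determines the generator's output.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n = 192,
                             wavelengths = seq(1100, 2498, by = 2),
                             dmd_mean = 0.74, dmd_sd = 0.03,
                             dmd_range = c(0, 0.95),
                             composition_cv = 0.10,
                             component_bands = default_component_bands(),
                             peg_bands = default_peg_bands(),
                             marker_bands = default_marker_bands(),
                             scatter = TRUE,
                             gain_range = c(0.95, 1.05),
                             offset_range = c(-0.02, 0.02),
                             tilt_range = c(-0.01, 0.01),
                             noise_sd = 5e-4,
                             seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  all_bands <- c(lapply(component_bands, function(b) b$center),
                 list(peg_bands$center),
                 lapply(marker_bands, function(b) b$center))
  rng <- range(wavelengths)
  if (any(unlist(all_bands) < rng[1] | unlist(all_bands) > rng[2]))
    stop("band center outside the wavelength grid", call. = FALSE)
  structure(as.list(environment())[c(
    "n", "wavelengths", "dmd_mean", "dmd_sd", "dmd_range",
    "composition_cv", "component_bands", "peg_bands", "marker_bands",
    "scatter", "gain_range", "offset_range", "tilt_range", "noise_sd",
    "seed")], class = "synthetic_config")
}

#' Render a gaussian band set as a spectrum profile
#'
#' @param wavelengths Grid in nm.
#' @param bands data.frame with `center`, `width` (gaussian sd, nm) and
#'   `height` columns.
#' @return Numeric profile vector on the grid.
#' @export
band_profile <- function(wavelengths, bands) {
  out <- numeric(length(wavelengths))
  for (i in seq_len(nrow(bands)))
    out <- out + bands$height[i] *
      exp(-0.5 * ((wavelengths - bands$center[i]) / bands$width[i])^2)
  out
}

# nominal dry-excreta organic mass fractions used as composition means
nominal_composition <- c(protein = 0.25, carbohydrate = 0.45,
                         lipid = 0.10, water = 0.08, baseline = 1.00)

draw_truncated_normal <- function(n, mean, sd, range) {
  out <- numeric(n)
  rejected <- 0L
  filled <- 0L
  while (filled < n) {
    draw <- stats::rnorm(n - filled, mean, sd)
    ok <- draw > range[1] & draw < range[2]
    rejected <- rejected + sum(!ok)
    keep <- draw[ok]
    out[filled + seq_along(keep)] <- keep
    filled <- filled + length(keep)
  }
  if (rejected > 0.01 * n)
    message("DMD truncation rejected ", rejected, " draws (",
            round(100 * rejected / (n + rejected), 1), "% of attempts)")
  out
}

apply_scatter_artifacts <- function(S, wavelengths, cfg) {
  n <- nrow(S)
  gain <- stats::runif(n, cfg$gain_range[1], cfg$gain_range[2])
  offset <- stats::runif(n, cfg$offset_range[1], cfg$offset_range[2])
  tilt <- stats::runif(n, cfg$tilt_range[1], cfg$tilt_range[2])
  wn <- (wavelengths - mean(range(wavelengths))) / (diff(range(wavelengths)) / 2)
  gain * S + offset + tilt %o% wn
}

#' Simulate an excreta spectra + reference dataset
#'
#' Per sample: DMD is drawn from the configured truncated normal; every
#' marker's excreta concentration follows by exact mass balance,
#' `excreta = diet / (1 - DMD)`; the clean spectrum is the Beer-Lambert
#' sum of component profiles weighted by randomly perturbed organic mass
#' fractions plus the PEG and marker organo-complex contributions; the
#' scatter artifact and noise are applied last. The reference table
#' carries the marker concentrations and the true DMD.
#'
#' @param cfg A `synthetic_config`.
#' @param diet A `diet_spec`.
#' @return List with `spectra` (a `spectra_set`; its `meta` holds the
#'   scatter parameters) and `reference` (a `reference_table` with
#'   `Yb_g_kg`, `Ti_g_kg`, `PEG_pct`, `DMD`). The per-sample organic
#'   composition matrix is attached as attribute `"composition"` for
#'   oracle-style recomputation.
#' @export
simulate_excreta_dataset <- function(cfg = synthetic_config(),
                                     diet = diet_spec()) {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(diet, "diet_spec"))
  w <- cfg$wavelengths
  profiles <- vapply(cfg$component_bands, band_profile,
                     numeric(length(w)), wavelengths = w)
  peg_prof <- band_profile(w, cfg$peg_bands)
  yb_prof <- band_profile(w, cfg$marker_bands$Yb)
  ti_prof <- band_profile(w, cfg$marker_bands$Ti)

  withr_seed(cfg$seed, {
    n <- cfg$n
    dmd <- draw_truncated_normal(n, cfg$dmd_mean, cfg$dmd_sd,
                                 cfg$dmd_range)
    yb_ex <- diet$yb_pct / (1 - dmd) * 10   # % -> g/kg
    ti_ex <- diet$ti_pct / (1 - dmd) * 10
    peg_ex <- diet$peg_pct / (1 - dmd)      # % of DM

    nom <- nominal_composition[colnames(profiles)]
    sdlog <- sqrt(log(1 + cfg$composition_cv^2))
    comp <- matrix(stats::rlnorm(n * length(nom),
                                 meanlog = log(nom) - sdlog^2 / 2,
                                 sdlog = sdlog),
                   n, length(nom), byrow = TRUE,
                   dimnames = list(NULL, names(nom)))
    S <- comp %*% t(profiles) +
      (peg_ex / 100) %o% peg_prof +
      yb_ex %o% yb_prof + ti_ex %o% ti_prof
    meta <- data.frame(dmd_true = dmd)
    if (cfg$scatter) S <- apply_scatter_artifacts(S, w, cfg)
    if (cfg$noise_sd > 0)
      S <- S + matrix(stats::rnorm(length(S), 0, cfg$noise_sd),
                      nrow(S), ncol(S))
    ids <- sprintf("S%03d", seq_len(n))
    out <- list(
      spectra = spectra_set(ids, w, S, meta = meta),
      reference = reference_table(ids, Yb_g_kg = yb_ex, Ti_g_kg = ti_ex,
                                  PEG_pct = peg_ex, DMD = dmd))
    attr(out, "composition") <- comp
    out
  })
}

#' Build the PEG ad hoc spiking design
#'
#' Emulates the fortified-sample calibration set: a single pooled
#' excreta spectrum (collected before marker dosing, so PEG- and
#' marker-free) is spiked with PEG at the given levels. Each spiked
#' spectrum is the mass-fraction mixture `(1 - w) * base + w * PEG
#' profile` with `w` the PEG mass fraction, then scatter and noise are
#' applied as configured. The default plan runs levels 0-15% in 1%
#' increments with duplicates at 0-10%, 27 samples in all.
#'
#' @param cfg A `synthetic_config` (its `n` is ignored; the plan sets
#'   the sample count).
#' @param base Pooled base spectrum on `cfg$wavelengths`; default is the
#'   nominal-composition organic mixture.
#' @param levels PEG levels in `%` (default `0:15`).
#' @param replicate_levels Levels receiving one extra replicate (default
#'   `0:10`, bringing 16 levels to 27 samples).
#' @return List with `spectra` and `reference` (column `PEG_pct`); the
#'   noise-free spectra are attached as attribute `"clean"`.
#' @export
spike_peg_design <- function(cfg = synthetic_config(), base = NULL,
                             levels = 0:15, replicate_levels = 0:10) {
  stopifnot(inherits(cfg, "synthetic_config"))
  w <- cfg$wavelengths
  if (is.null(base)) {
    profiles <- vapply(cfg$component_bands, band_profile,
                       numeric(length(w)), wavelengths = w)
    base <- drop(profiles %*% nominal_composition[colnames(profiles)])
  }
  if (length(base) != length(w))
    stop("base spectrum not on cfg's wavelength grid", call. = FALSE)
  all_levels <- sort(c(levels, replicate_levels))
  if (any(all_levels < 0 | all_levels >= 100))
    stop("PEG levels must lie in [0, 100) percent", call. = FALSE)
  peg_prof <- band_profile(w, cfg$peg_bands)
  withr_seed(cfg$seed, {
    wfrac <- all_levels / 100
    S <- (1 - wfrac) %o% base + wfrac %o% peg_prof
    if (cfg$scatter) S <- apply_scatter_artifacts(S, w, cfg)
    clean <- S
    if (cfg$noise_sd > 0)
      S <- S + matrix(stats::rnorm(length(S), 0, cfg$noise_sd),
                      nrow(S), ncol(S))
    ids <- make.unique(sprintf("PEG%04.1f", all_levels), sep = "_r")
    out <- list(
      spectra = spectra_set(ids, w, S,
                            meta = data.frame(peg_level = all_levels)),
      reference = reference_table(ids, PEG_pct = all_levels))
    attr(out, "clean") <- clean
    out
  })
}
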