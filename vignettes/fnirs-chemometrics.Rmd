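---
title: "Chemometric methods for fecal NIRS digestibility calibrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemometric methods for fecal NIRS digestibility calibrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirscal)
```

## The measurement model

Fecal NIRS digestibility studies rest on two models stacked on top of
each other.

The first is mass balance. An indigestible marker dosed into feed at
concentration $c_d$ leaves the bird entirely in excreta; if a fraction
$\mathrm{DMD}$ of the dry matter disappears, the marker concentrates to
$c_e = c_d / (1 - \mathrm{DMD})$, so

$$\mathrm{DMD} = 1 - \frac{c_d}{c_e}.$$

`dmd_from_marker()` is this formula; it refuses a zero excreta
concentration and warns on a negative result (marker more dilute in
excreta than in feed), which in practice signals incomplete recovery or
a units mistake. Because diets dose oxides (TiO$_2$, Yb$_2$O$_3$) while
assays report elements, `oxide_to_element()` converts with the standard
atomic-mass fractions (Ti/TiO$_2$ = 47.8670/79.8650, 2Yb/Yb$_2$O$_3$ =
346.0900/394.0870); both sides of the ratio must share one basis and
unit, and `marker_measurement()` enforces that rather than guessing.

The second is the spectroscopic calibration: dried, ground excreta is
scanned in reflectance (absorbance recorded as $\log_{10}(1/R)$ on a
uniform grid, duplicate cup fillings averaged), and the marker
concentration is predicted from the spectrum by partial least squares
after scatter correction. Minerals have no NIR absorption of their own;
what the calibration sees are the organo-mineral complexes the marker
forms in the excreta matrix, which is why these models work at all and
also why they rarely exceed screening quality on real data.

## Preprocessing

Particle-size and packing differences show up as per-sample affine
distortions of the spectrum. The package implements the four standard
corrections: SNV (per-spectrum standardization), detrend (residual of a
least-squares polynomial in wavelength; order 2, the conventional "D"),
SNV+D (SNV then detrend), and MSC (each spectrum regressed on a
reference and inverted, $(x - a)/b$). The MSC reference is the
calibration-set mean, fixed when the recipe is fitted and reused
unchanged for validation and routine spectra — letting the reference
drift with the prediction set would leak information across the split.

Derivatives follow the WinISI four-digit convention `d.g.s1.s2`:
running-average smoothing of widths `s1` then `s2`, then differencing
over a gap of `g` points — first derivative
$\bar a(i + \lceil g/2 \rceil) - \bar a(i - \lfloor g/2 \rfloor)$,
second $\bar a(i-g) - 2\bar a(i) + \bar a(i+g)$. Points whose window is
incomplete are dropped and the grid shortened: truncation invents no
data, padding would. The exact commercial implementation is
proprietary; this gap-segment form is the published convention, and two
of its unstated choices are surfaced as code defaults rather than
hidden: the asymmetric floor/ceil offsets for odd gaps, and smoothing
*before* differencing. Scatter correction is applied before the
derivative, the common usage; the recipe object makes the order
explicit and loggable. Savitzky–Golay derivatives are deliberately not
offered — they are a different operator than what the four-digit code
denotes.

## Modified PLS and factor selection

The regression is NIPALS PLS1 on mean-centered data. The "modified"
variant (MPLS), the default in WinISI and here, additionally divides
each X-residual column and the y-residual by their standard deviations
after every factor extraction, damping high-variance spectral regions
in later factors. Every step of that recursion is affine in the input
spectrum, so predictions still reduce to `intercept + X %*% coefficients`;
the coefficients are recovered by pushing the unit basis through the
recursion and stored on the model. With one factor the two variants
coincide, which the tests assert; the standard variant is also checked
against an independent NIPALS implementation and, at full rank, against
the pseudoinverse least-squares fit.

Cross-validation uses contiguous fold blocks over one seeded shuffle
(6 folds by default, per-fold refits, SECV $= \sqrt{\sum_i (\hat y_{cv,i} -
y_i)^2 / n}$). The paper-style protocol reports only the chosen model;
the selection rule itself is not published, so the package uses the
"fewest factors near the minimum" heuristic: the smallest factor count
whose SECV is within 2% of the curve minimum (`secv_slack = 1.02`,
configurable). The calibration/validation split defaults to
rank-stratified — every 4th sample by sorted analyte value goes to
validation, offset so the extremes stay in calibration — because a 25%
random draw at these sample sizes routinely leaves the validation set
range-deficient; a seeded random strategy is available.

## Outlier elimination

Two passes, both statistics computed jointly each pass: chemical
outliers at $t = |\hat y - y| / \mathrm{SEC} \ge 2.5$ and spectral
outliers at $GH = D^2_{\mathrm{Mahalanobis}} / a \ge 10$ in the
$a$-factor score space. Removals are cumulative-capped at 10% of the
starting samples; when flags exceed the cap, the worst offenders by
$\max(t/t_{crit}, GH/h_{crit})$ go first, a rule chosen for
determinism and order-independence since the source protocol is silent
on ties. SEC (not SECV) sits in the t denominator — the WinISI pairing
— behind a flag. The GH threshold of 10 is kept as the protocol states
it even though much of the NIRS literature screens at 3; it is a
config default, not a constant. Note that $t$ is scale-free: on any
finite clean sample a few points can exceed 2.5 by chance, so "no
outliers" is a property of a dataset instance, not of the noise level.

## Figures of merit and quality classes

`validation_stats()` reports bias $= \overline{\hat y - y}$,
bias-corrected SEP (with the uncorrected RMSEP alongside, since
reports rarely say which they used), slope of reference on predicted
(the WinISI convention; the alternate slope is also logged), $R^2$ as
squared correlation, RPD $= \mathrm{SD}/\mathrm{SEP}$ and RER $=
\mathrm{range}/\mathrm{SEP}$. The two ratios share the SEP, so
RER/RPD $=$ range/SD identically — a consistency the tests verify on
every report. Classification: quantitative at RPD $\ge 3$ and RER
$\ge 10$; 2.5–3.0 screening; 2.0–2.5 acceptable for specific
compounds; below 2.0 unreliable.

`grid_search()` runs the whole protocol (split → recipe fit → outlier
passes → CV → external validation) for each scatter × treatment
combination — the canonical grid is 4 × 4 — and ranks by R²_CV, then
SECV, then factor count; ties beyond that are broken by recipe name so
reruns are stable.

## What the synthetic generator does and does not emulate

No raw spectra are publicly available for the kind of broiler excreta
study this workflow targets, so
`simulate_excreta_dataset()` generates them: each spectrum is a
Beer–Lambert sum of synthetic gaussian band profiles (protein,
carbohydrate, lipid, residual water, a broad baseline; band positions
near standard NIR assignments but invented in height and width), plus
a pure-PEG profile and marker organo-complex signatures whose
amplitudes scale with concentration. Organic mass fractions vary
lognormally across samples (CV 10%); DMD is drawn from a normal
truncated to (0, 0.95) with mean 0.74 and SD 0.03, matching the
reported population; marker concentrations follow by exact mass
balance, which propagates to the ≈11% concentration CV the study
tables show. Scatter artifacts (gain 0.95–1.05, offset ±0.02, tilt
±0.01) are applied after mixing and white absorbance noise (sd 5e-4,
typical instrument noise) last, mirroring measurement order. One seed
determines everything, and the generator restores the caller's RNG
state.

The spiking design `spike_peg_design()` reproduces the fortified-sample
plan: levels 0–15% in 1% steps with duplicates at 0–10%, 27 samples.
Published descriptions of this design disagree on the replicate
structure (27 fortified samples in one place, n = 51 in another), so
the plan is configurable and the default favors dense support at low
PEG, where prediction matters. The re-wetting and re-drying of real
fortified samples is not modeled.

Limits worth keeping in mind when reading test results: the generator
has no radiative-transfer or particle-size physics — its scatter
artifacts are exactly the affine family SNV/MSC are designed to remove,
so preprocessing looks somewhat better here than on real powders. All
markers share one true DMD and carry no assay noise in the reference
table (mass balance is exact by construction), so cross-marker DMD
agreement is trivially $r^2 = 1$ and marker calibrations for Ti and Yb
are statistically twins; real data adds per-assay noise, incomplete
recovery and diet-dependent matrix effects that this generator
deliberately omits. Passing tests therefore demonstrate that the
machinery is correct, not that field performance will match.

A related note on units: reported excreta marker concentrations in this
literature often cannot be reconciled with the stated diet doses through the
mass-balance formula under any single unit/basis convention, which is
precisely why every concentration in this package carries explicit
units and basis and mixed-basis ratios are refused. The generator keeps
mass balance exact on the element basis rather than chasing the printed
absolute scale; only the dispersion (CV) and the DMD distribution are
matched.

## Numerical choices and problem sizes

* Grid: 1100–2498 nm at 2 nm (700 points) by default. The instrument
  description ("2 nm intervals, 692 data points over 1100–2500 nm") is
  internally inconsistent — the arithmetic gives 701 — so the grid is a
  configuration value, never a hard-coded length.
* Absorbance uses log base 10 (the NIR convention; reports often write
  log(1/R) without a base).
* Degenerate inputs error loudly: constant spectra in SNV, MSC slopes
  below 1e-8, zero-variance responses, saturated SEC denominators,
  singular score covariances.
* Running-average windows of even width place the extra point forward,
  matching `stats::filter`; both smoothing passes happen before
  differencing.
* Model files round-trip exactly: scalars ride in JSON for
  readability, and every number that must reload bit-identically is
  written at 17 significant digits in the companion array CSV.
* Test and example problem sizes are deliberately modest — 27-sample
  spiking sets, 32–192-sample simulated studies, coarse 175-point
  grids where the full 700-point grid adds nothing — because the
  assertions are about correctness (oracle equality, analytic
  identities, exact round-trips), which does not improve with scale.
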