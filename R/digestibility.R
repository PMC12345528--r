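# standard atomic masses (IUPAC conventional, 4 decimals)
.atomic_mass <- c(Ti = 47.8670, Yb = 173.0450, O = 15.9990)

#' Convert an oxide amount to its element amount
#'
#' Multiplies by the element mass fraction of the dosed compound:
#' `Ti/TiO2 = 47.8670 / 79.8650` and `2*Yb/Yb2O3 = 346.0900 /
#' 394.0870`. The conversion is linear, so it commutes with addition
#' and with the mass-balance ratio. Any unit (g/kg, mg/kg, %) passes
#' through unchanged.
#'
#' @param amount Non-negative numeric vector (oxide basis).
#' @param species `"TiO2"` or `"Yb2O3"`.
#' @return Element amount(s) in the same units.
#' @export
#' @examples
#' oxide_to_element(2, "TiO2")       # g/kg Ti from 2 g/kg TiO2
#' oxide_to_element(50, "Yb2O3")     # mg/kg Yb from 50 mg/kg Yb2O3
oxide_to_element <- function(amount, species) {
  if (any(amount < 0)) stop("amount must be >= 0", call. = FALSE)
  frac <- switch(species,
    TiO2 = .atomic_mass[["Ti"]] /
      (.atomic_mass[["Ti"]] + 2 * .atomic_mass[["O"]]),
    Yb2O3 = 2 * .atomic_mass[["Yb"]] /
      (2 * .atomic_mass[["Yb"]] + 3 * .atomic_mass[["O"]]),
    stop("unknown species '", species, "'; use 'TiO2' or 'Yb2O3'",
         call. = FALSE))
  amount * frac
}

#' A marker measurement pair (diet and excreta concentrations)
#'
#' Carries the two concentrations the digestibility formula needs and
#' enforces that both sides share the same basis and units: ratios of
#' mixed element/oxide values are refused rather than silently wrong.
#'
#' @param marker One of `"Yb"`, `"Ti"`, `"PEG"`, `"ADF"`.
#' @param diet Marker concentration in the diet (% of DM).
#' @param excreta Marker concentration(s) in excreta (% of DM); may be a
#'   vector of per-sample values.
#' @param basis `"element"` or `"oxide"`; must describe both sides.
#' @return A `marker_measurement` object.
#' @export
marker_measurement <- function(marker = c("Yb", "Ti", "PEG", "ADF"),
                               diet, excreta,
                               basis = c("element", "oxide")) {
  marker <- match.arg(marker)
  basis <- match.arg(basis)
  if (any(diet < 0) || any(excreta < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  structure(list(marker = marker, diet = diet, excreta = excreta,
                 basis = basis), class = "marker_measurement")
}

#' Dry-matter digestibility from an indigestible marker
#'
#' `DMD = 1 - diet / excreta`: the indigestible marker concentrates in
#' excreta exactly in proportion to the dry matter that disappears.
#' Both concentrations must be on the same basis and in the same units
#' (use a [marker_measurement()] to have that enforced). A negative DMD
#' — the marker more dilute in excreta than in feed — is returned with a
#' warning since it signals marker dilution or a unit error.
#'
#' @param diet Diet marker concentration, or a `marker_measurement`
#'   (then `excreta` is ignored).
#' @param excreta Excreta marker concentration(s) > 0.
#' @return DMD fraction(s).
#' @export
#' @examples
#' dmd_from_marker(0.2, 0.8)  # 0.75
dmd_from_marker <- function(diet, excreta = NULL) {
  if (inherits(diet, "marker_measurement")) {
    excreta <- diet$excreta
    diet <- diet$diet
  }
  if (any(excreta == 0))
    stop("excreta marker concentration of 0: DMD undefined",
         call. = FALSE)
  dmd <- 1 - diet / excreta
  if (any(dmd < 0))
    warning("negative DMD (marker more dilute in excreta than in diet); ",
            "check units/basis")
  dmd
}

#' Pairwise agreement of marker-based DMD estimates
#'
#' Squared Pearson correlation for every pair of DMD columns; symmetric
#' with unit diagonal. A zero-variance column makes its pairs undefined
#' (NA, with a warning).
#'
#' @param dmd_table data.frame or matrix, one column per marker, one row
#'   per sample (>= 3 complete rows per pair).
#' @return Symmetric matrix of r-squared values.
#' @export
marker_agreement <- function(dmd_table) {
  M <- as.matrix(dmd_table)
  if (nrow(M) < 3) stop("need at least 3 samples", call. = FALSE)
  sds <- apply(M, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE))
    warning("zero-variance DMD column(s): ",
            paste(colnames(M)[which(sds == 0)], collapse = ", "),
            "; their pairs are undefined")
  r <- suppressWarnings(
    stats::cor(M, use = "pairwise.complete.obs"))
  r2 <- r^2
  diag(r2) <- 1
  r2
}
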