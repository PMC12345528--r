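#' Parse a WinISI-style math treatment code
#'
#' The four-digit code "d.g.s1.s2" gives the derivative order d (0, 1 or
#' 2), the gap g in data points over which the derivative is taken, and
#' the widths s1, s2 (points) of the first and second running-average
#' smoothing passes.
#'
#' @param code Character, e.g. `"1.4.4.1"`, or an existing
#'   `math_treatment`.
#' @return A `math_treatment` object with fields `d`, `g`, `s1`, `s2`.
#' @export
#' @examples
#' math_treatment("2.5.5.1")
math_treatment <- function(code) {
  if (inherits(code, "math_treatment")) return(code)
  parts <- suppressWarnings(as.integer(strsplit(code, ".", fixed = TRUE)[[1]]))
  if (length(parts) != 4 || anyNA(parts))
    stop("math treatment must be four dot-separated integers 'd.g.s1.s2', got '",
         code, "'", call. = FALSE)
  d <- parts[1]; g <- parts[2]; s1 <- parts[3]; s2 <- parts[4]
  if (!d %in% 0:2) stop("derivative order must be 0, 1 or 2", call. = FALSE)
  if (g < 1 || s1 < 1 || s2 < 1)
    stop("gap and smoothing widths must be >= 1", call. = FALSE)
  structure(list(d = d, g = g, s1 = s1, s2 = s2), class = "math_treatment")
}

#' @export
format.math_treatment <- function(x, ...)
  paste(x$d, x$g, x$s1, x$s2, sep = ".")

#' @export
print.math_treatment <- function(x, ...) {
  cat("<math_treatment> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Standard normal variate transform
#'
#' Centers and scales each spectrum (row) to mean 0 and sample standard
#' deviation 1, removing multiplicative and additive scatter per spectrum.
#'
#' @param A Numeric matrix (samples x wavelengths) or a single spectrum.
#' @return Transformed matrix/vector of the same shape.
#' @export
snv <- function(A) {
  vec <- !is.matrix(A)
  if (vec) A <- matrix(A, nrow = 1)
  if (ncol(A) < 2) stop("SNV needs at least 2 wavelengths", call. = FALSE)
  mu <- rowMeans(A)
  sd_ <- sqrt(rowSums((A - mu)^2) / (ncol(A) - 1))
  if (any(sd_ < 1e-12))
    stop("degenerate (constant) spectrum at row ",
         which(sd_ < 1e-12)[1], ": SNV undefined", call. = FALSE)
  out <- (A - mu) / sd_
  if (vec) drop(out) else out
}

#' Polynomial detrend
#'
#' Removes, per spectrum, the least-squares polynomial of `order` in
#' wavelength, returning the residual. Order 2 is the conventional "D" of
#' SNV+D.
#'
#' @param A Matrix (samples x wavelengths) or single spectrum.
#' @param wavelengths Wavelength grid (nm).
#' @param order Polynomial degree (default 2).
#' @return Residual spectra, same shape as `A`.
#' @export
detrend <- function(A, wavelengths, order = 2) {
  vec <- !is.matrix(A)
  if (vec) A <- matrix(A, nrow = 1)
  p <- ncol(A)
  if (length(wavelengths) != p)
    stop("wavelength grid length mismatch", call. = FALSE)
  if (p <= order + 1)
    stop("need more than order+1 = ", order + 1, " points to detrend",
         call. = FALSE)
  # orthonormal polynomial basis; projection removes the fitted polynomial
  B <- cbind(1 / sqrt(p), stats::poly(wavelengths, degree = order))
  qrB <- qr(B)
  if (qrB$rank < ncol(B))
    stop("rank-deficient polynomial basis (degenerate grid)", call. = FALSE)
  out <- A - t(qr.fitted(qrB, t(A)))
  if (vec) drop(out) else out
}

#' Multiplicative scatter correction
#'
#' Each spectrum x is regressed on a reference spectrum, x = a + b * ref,
#' and returned as (x - a) / b. The reference is conventionally the mean
#' calibration spectrum, fixed at fit time and reused unchanged for any
#' later (validation or routine) spectra.
#'
#' @param A Matrix (samples x wavelengths) or single spectrum.
#' @param reference Reference spectrum on the same grid.
#' @return Corrected spectra, same shape as `A`.
#' @export
msc <- function(A, reference) {
  vec <- !is.matrix(A)
  if (vec) A <- matrix(A, nrow = 1)
  reference <- as.numeric(reference)
  if (length(reference) != ncol(A))
    stop("MSC reference not on the spectra's grid", call. = FALSE)
  rc <- reference - mean(reference)
  vr <- sum(rc^2)
  if (vr < 1e-20) stop("constant MSC reference", call. = FALSE)
  b <- drop(A %*% rc) / vr
  if (any(abs(b) < 1e-8))
    stop("degenerate spectrum at row ", which(abs(b) < 1e-8)[1],
         ": MSC slope ~ 0", call. = FALSE)
  a <- rowMeans(A) - b * mean(reference)
  out <- (A - a) / b
  if (vec) drop(out) else out
}

# centered running mean of width s along rows; NA where window incomplete.
# window spans floor((s-1)/2) points back and ceil((s-1)/2) forward (the
# extra point of an even window lies forward, matching stats::filter).
running_mean <- function(A, s) {
  if (s <= 1) return(A)
  p <- ncol(A)
  lo <- floor((s - 1) / 2)
  hi <- (s - 1) - lo
  out <- matrix(NA_real_, nrow(A), p)
  cs <- cbind(0, t(apply(A, 1, cumsum)))
  j <- seq(1 + lo, p - hi)
  out[, j] <- (cs[, j + hi + 1, drop = FALSE] -
                 cs[, j - lo, drop = FALSE]) / s
  out
}

#' Norris gap-segment derivative
#'
#' The spectra are smoothed with running means of widths s1 then s2, and
#' differenced over a gap of g points: first derivative
#' `sm(i + ceil(g/2)) - sm(i - floor(g/2))`, second derivative
#' `sm(i - g) - 2 sm(i) + sm(i + g)`. Edge points whose smoothing or
#' difference window is incomplete are dropped and the wavelength grid
#' shortened accordingly (truncation, never padding). With d = 0 the
#' result is the doubly smoothed spectrum.
#'
#' @param A Matrix (samples x wavelengths).
#' @param wavelengths Wavelength grid matching `ncol(A)`.
#' @param treatment A `math_treatment` or its "d.g.s1.s2" code.
#' @return List with elements `absorbance` (matrix) and `wavelengths`
#'   (shortened grid).
#' @export
gap_segment_derivative <- function(A, wavelengths, treatment) {
  tr <- math_treatment(treatment)
  p <- ncol(A)
  need <- max(tr$s1, tr$s2) + if (tr$d == 0) 0 else 2 * tr$g
  if (p < need)
    stop("spectrum of length ", p, " too short for treatment ",
         format(tr), "; need at least ", need, " points", call. = FALSE)
  S <- running_mean(running_mean(A, tr$s1), tr$s2)
  g <- tr$g
  idx <- seq_len(p)
  if (tr$d == 0) {
    D <- S
  } else if (tr$d == 1) {
    lo <- floor(g / 2); hi <- ceiling(g / 2)
    j <- seq(1 + lo, p - hi)
    D <- matrix(NA_real_, nrow(A), p)
    D[, j] <- S[, j + hi, drop = FALSE] - S[, j - lo, drop = FALSE]
  } else {
    j <- seq(1 + g, p - g)
    D <- matrix(NA_real_, nrow(A), p)
    D[, j] <- S[, j - g, drop = FALSE] - 2 * S[, j, drop = FALSE] +
      S[, j + g, drop = FALSE]
  }
  keep <- which(colSums(is.na(D)) == 0)
  list(absorbance = D[, keep, drop = FALSE], wavelengths = wavelengths[keep])
}

#' Define a preprocessing recipe
#'
#' A recipe is a scatter correction (`"none"`, `"SNV"`, `"D"`, `"SNV+D"`
#' or `"MSC"`) followed by a gap-segment derivative math treatment.
#' Recipes are written `"SNV+D/2.4.4.1"`. An MSC recipe stores the
#' calibration mean spectrum when fitted and reuses it unchanged.
#'
#' @param scatter Scatter correction name, or a full `"scatter/d.g.s1.s2"`
#'   string when `treatment` is missing.
#' @param treatment A math treatment code or `math_treatment`.
#' @param detrend_order Polynomial degree used by "D" (default 2).
#' @return A `recipe` object.
#' @export
#' @examples
#' recipe("SNV", "1.4.4.1")
#' recipe("MSC/2.5.5.1")
recipe <- function(scatter = "none", treatment = "0.1.1.1",
                   detrend_order = 2) {
  if (missing(treatment) && grepl("/", scatter, fixed = TRUE)) {
    parts <- strsplit(scatter, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("recipe string must be 'scatter/d.g.s1.s2'", call. = FALSE)
    scatter <- parts[1]; treatment <- parts[2]
  }
  scatter <- match.arg(scatter, c("none", "SNV", "D", "SNV+D", "MSC"))
  structure(list(scatter = scatter, treatment = math_treatment(treatment),
                 detrend_order = detrend_order, msc_reference = NULL),
            class = "recipe")
}

#' @export
format.recipe <- function(x, ...)
  paste0(x$scatter, "/", format(x$treatment))

#' @export
print.recipe <- function(x, ...) {
  cat("<recipe> ", format(x),
      if (x$scatter == "MSC" && !is.null(x$msc_reference)) " (MSC fitted)",
      "\n", sep = "")
  invisible(x)
}

#' Fit a recipe's data-dependent parts on calibration spectra
#'
#' Only MSC has a fitted component (the stored reference spectrum, the
#' calibration mean). Other recipes are returned unchanged, so fitting is
#' always safe to call.
#'
#' @param rec A `recipe`.
#' @param spectra Calibration `spectra_set`.
#' @return The fitted `recipe`.
#' @export
fit_recipe <- function(rec, spectra) {
  stopifnot(inherits(rec, "recipe"))
  if (rec$scatter == "MSC")
    rec$msc_reference <- colMeans(spectra$absorbance)
  rec
}

#' Apply a preprocessing recipe
#'
#' Scatter correction is applied first (SNV+D = SNV then detrend), then
#' the gap-segment derivative treatment, which shortens the grid at the
#' edges.
#'
#' @param spectra A `spectra_set`.
#' @param rec A `recipe`; if it uses MSC it must have been fitted with
#'   [fit_recipe()].
#' @return A preprocessed `spectra_set` on a possibly shortened grid.
#' @export
apply_recipe <- function(spectra, rec) {
  stopifnot(inherits(rec, "recipe"))
  validate_spectra_set(spectra)
  A <- spectra$absorbance
  w <- spectra$wavelengths
  A <- switch(rec$scatter,
    "none"  = A,
    "SNV"   = snv(A),
    "D"     = detrend(A, w, rec$detrend_order),
    "SNV+D" = detrend(snv(A), w, rec$detrend_order),
    "MSC"   = {
      if (is.null(rec$msc_reference))
        stop("MSC recipe must be fitted with fit_recipe() before use",
             call. = FALSE)
      msc(A, rec$msc_reference)
    })
  d <- gap_segment_derivative(A, w, rec$treatment)
  spectra_set(spectra$sample_ids, d$wavelengths, d$absorbance,
              meta = spectra$meta)
}
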