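#' Construct a SpectraSet
#'
#' The container every pipeline stage transforms: a set of NIR spectra on a
#' shared wavelength grid, stored as absorbance (log10(1/R)), with one row
#' per sample and optional per-sample metadata.
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param wavelengths Numeric vector of wavelengths in nm; strictly
#'   increasing with constant spacing (2 nm on the FOSS-style grid).
#' @param absorbance Numeric matrix, samples x wavelengths, of log10(1/R)
#'   values. All values must be finite.
#' @param meta Optional data.frame of per-sample metadata (diet, cereal,
#'   enzyme, collection day, replicate label, ...), one row per sample.
#' @param check Logical; validate invariants (default `TRUE`).
#'
#' @return An object of class `spectra_set` with elements `sample_ids`,
#'   `wavelengths`, `absorbance` and `meta`.
#' @export
spectra_set <- function(sample_ids, wavelengths, absorbance, meta = NULL,
                        check = TRUE) {
  sample_ids <- as.character(sample_ids)
  wavelengths <- as.numeric(wavelengths)
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  if (is.null(meta)) {
    meta <- data.frame(row.names = seq_along(sample_ids))
  }
  obj <- structure(
    list(sample_ids = sample_ids, wavelengths = wavelengths,
         absorbance = absorbance, meta = meta),
    class = "spectra_set")
  if (check) validate_spectra_set(obj)
  dimnames(obj$absorbance) <- list(sample_ids, format_nm(wavelengths))
  obj
}

format_nm <- function(w) {
  # wavelength column headers; trim fractional trailing zeros only
  x <- format(w, trim = TRUE, scientific = FALSE)
  has_dec <- grepl(".", x, fixed = TRUE)
  x[has_dec] <- sub("\\.?0+$", "", x[has_dec])
  x
}

validate_spectra_set <- function(x) {
  stopifnot(inherits(x, "spectra_set"))
  n <- length(x$sample_ids)
  p <- length(x$wavelengths)
  if (nrow(x$absorbance) != n)
    stop("absorbance has ", nrow(x$absorbance), " rows but there are ",
         n, " sample ids", call. = FALSE)
  if (ncol(x$absorbance) != p)
    stop("absorbance has ", ncol(x$absorbance), " columns but there are ",
         p, " wavelengths", call. = FALSE)
  if (p >= 2) check_uniform_grid(x$wavelengths)
  if (!all(is.finite(x$absorbance)))
    stop("absorbance contains non-finite values", call. = FALSE)
  if (nrow(x$meta) != n)
    stop("meta has ", nrow(x$meta), " rows for ", n, " samples",
         call. = FALSE)
  invisible(x)
}

check_uniform_grid <- function(w, tol = 1e-8) {
  d <- diff(w)
  if (any(d <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (max(d) - min(d) > tol * max(abs(w)))
    stop("wavelength grid is not uniformly spaced: spacings range ",
         format(min(d)), " to ", format(max(d)), " nm", call. = FALSE)
  invisible(d[1])
}

#' @export
print.spectra_set <- function(x, ...) {
  w <- x$wavelengths
  cat("<spectra_set> ", length(x$sample_ids), " samples x ",
      length(w), " wavelengths (", w[1], "-", w[length(w)], " nm, ",
      if (length(w) >= 2) diff(w[1:2]) else NA, " nm step)\n", sep = "")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

#' Subset a SpectraSet by sample and/or wavelength
#'
#' @param x A `spectra_set`.
#' @param i Sample selector (indices, logical, or sample ids).
#' @param j Wavelength selector (indices or logical over the grid).
#' @param ... Ignored.
#' @return A `spectra_set`.
#' @export
`[.spectra_set` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$sample_ids)
  if (missing(j)) j <- seq_along(x$wavelengths)
  if (is.character(i)) i <- match(i, x$sample_ids)
  if (anyNA(i)) stop("unknown sample id in subset", call. = FALSE)
  spectra_set(x$sample_ids[i], x$wavelengths[j],
              x$absorbance[i, j, drop = FALSE],
              meta = x$meta[i, , drop = FALSE])
}

#' Convert reflectance to absorbance
#'
#' Absorbance is recorded as log10(1/R), R the reflected energy fraction.
#'
#' @param R Numeric matrix (or vector) of reflectance values in (0, 1].
#' @return Matrix of the same shape with `A = log10(1/R)`.
#' @export
#' @examples
#' reflectance_to_absorbance(c(1, 0.1, 0.01))  # 0 1 2
reflectance_to_absorbance <- function(R) {
  R <- if (is.matrix(R)) R else as.numeric(R)
  bad <- which(!(R > 0))
  if (length(bad)) {
    loc <- if (is.matrix(R)) {
      ij <- arrayInd(bad[1], dim(R))
      paste0("sample row ", ij[1], ", wavelength column ", ij[2])
    } else paste0("position ", bad[1])
    stop("reflectance must be > 0; first offending value at ", loc,
         call. = FALSE)
  }
  log10(1 / R)
}

#' Average replicate scans into one spectrum per sample
#'
#' Duplicate cup fillings of the same sample are averaged wavelength by
#' wavelength. Replicate membership is taken from `meta[[id_col]]` when
#' present, otherwise from repeated `sample_ids`.
#'
#' @param spectra A `spectra_set` whose rows are replicate scans.
#' @param id_col Name of the metadata column holding the true sample id;
#'   defaults to using `sample_ids` directly.
#' @return A `spectra_set` with one row per sample, in order of first
#'   appearance; `meta$n_replicates` records how many scans were averaged.
#' @export
average_duplicates <- function(spectra, id_col = NULL) {
  validate_spectra_set(spectra)
  ids <- if (!is.null(id_col)) {
    if (!id_col %in% names(spectra$meta))
      stop("no metadata column '", id_col, "'", call. = FALSE)
    as.character(spectra$meta[[id_col]])
  } else spectra$sample_ids
  uniq <- unique(ids)
  A <- matrix(0, length(uniq), length(spectra$wavelengths))
  nrep <- integer(length(uniq))
  for (k in seq_along(uniq)) {
    rows <- which(ids == uniq[k])
    nrep[k] <- length(rows)
    A[k, ] <- colMeans(spectra$absorbance[rows, , drop = FALSE])
  }
  spectra_set(uniq, spectra$wavelengths, A,
              meta = data.frame(n_replicates = nrep))
}

#' Read a wide spectra table
#'
#' Expects a wide CSV: first column the sample id, remaining column headers
#' parseable as wavelengths in nm on a strictly increasing, uniformly
#' spaced grid.
#'
#' @param path Path to a CSV file (UTF-8, '.' decimal).
#' @return A `spectra_set`.
#' @export
read_spectra_table <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = NA),
    error = function(e) stop("cannot parse spectra table '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0 || ncol(df) < 2)
    stop("spectra table '", path,
         "' is empty or has no wavelength columns", call. = FALSE)
  w <- suppressWarnings(as.numeric(names(df)[-1]))
  if (anyNA(w))
    stop("non-numeric wavelength header(s): ",
         paste(names(df)[-1][is.na(w)][1:min(3, sum(is.na(w)))],
               collapse = ", "), call. = FALSE)
  check_uniform_grid(w)
  A <- as.matrix(df[, -1, drop = FALSE])
  spectra_set(df[[1]], w, A)
}

#' Write a SpectraSet as a wide CSV
#'
#' Values are written with 17 significant digits so that
#' `read_spectra_table(write_spectra_table(s))` round-trips exactly.
#'
#' @param spectra A `spectra_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(spectra, path) {
  validate_spectra_set(spectra)
  A <- spectra$absorbance
  txt <- matrix(sprintf("%.17g", A), nrow(A), ncol(A))
  df <- data.frame(sample_id = spectra$sample_ids, txt,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("sample_id", format_nm(spectra$wavelengths))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a reference table of analyte values
#'
#' A plain data.frame with a `sample_id` column and one named column per
#' analyte (e.g. `Yb_g_kg`, `Ti_g_kg`, `PEG_pct`, `DMD`). Concentrations
#' must be non-negative; a `DMD` column must lie below 1 (a fraction).
#'
#' @param sample_ids Character vector of ids.
#' @param ... Named numeric analyte vectors, one value per sample.
#' @return A data.frame of class `reference_table`.
#' @export
reference_table <- function(sample_ids, ...) {
  analytes <- list(...)
  df <- data.frame(sample_id = as.character(sample_ids),
                   stringsAsFactors = FALSE)
  for (nm in names(analytes)) {
    v <- as.numeric(analytes[[nm]])
    if (length(v) != nrow(df))
      stop("analyte '", nm, "' has length ", length(v), " for ",
           nrow(df), " samples", call. = FALSE)
    if (identical(nm, "DMD")) {
      if (any(v >= 1)) stop("DMD must be < 1 (a fraction)", call. = FALSE)
    } else if (any(v < 0, na.rm = TRUE)) {
      stop("analyte '", nm, "' has negative concentrations", call. = FALSE)
    }
    df[[nm]] <- v
  }
  class(df) <- c("reference_table", "data.frame")
  df
}

#' Align a reference table to a SpectraSet
#'
#' @param ref A `reference_table` (or data.frame with `sample_id`).
#' @param spectra A `spectra_set`.
#' @return `ref` reordered to the spectra's sample order.
#' @export
align_reference <- function(ref, spectra) {
  idx <- match(spectra$sample_ids, ref$sample_id)
  if (anyNA(idx))
    stop("reference table is missing sample(s): ",
         paste(utils::head(spectra$sample_ids[is.na(idx)], 3),
               collapse = ", "), call. = FALSE)
  ref[idx, , drop = FALSE]
}
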