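#' Construct a hyperspectral transmittance cube
#'
#' A `hyper_cube` is the package's central container: a 3-D numeric array
#' indexed `(row, col, band)` holding either raw detector counts or
#' calibrated transmittance, together with the wavelength axis (band
#' centers, nm) and free-form provenance metadata. Rows are the scan axis
#' of a line-scan (pushbroom) instrument; indexing is 1-based `(row, col)`.
#'
#' @param values numeric 3-D array, dimensions `(rows, cols, bands)`.
#' @param wavelengths numeric vector of band centers in nm, strictly
#'   increasing, length equal to `dim(values)[3]`.
#' @param meta named list of provenance (source file, calibration state,
#'   guard-pixel counts, ...). The logical entry `calibrated` marks a cube
#'   holding transmittance rather than counts.
#' @return an object of class `hyper_cube`.
#' @export
hyper_cube <- function(values, wavelengths, meta = list()) {
  values <- unclass(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-D array (row, col, band)")
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(values)[3L])
    stop(sprintf("wavelength axis has %d entries but cube has %d bands",
                 length(wavelengths), dim(values)[3L]))
  if (any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be strictly increasing")
  if (!is.list(meta)) stop("`meta` must be a list")
  if (isTRUE(meta$calibrated) && !all(is.finite(values)))
    stop("calibrated cube contains non-finite values")
  structure(list(values = values, wavelengths = wavelengths, meta = meta),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hyper_cube> %d x %d pixels, %d bands (%.1f-%.1f nm)%s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              if (isTRUE(x$meta$calibrated)) ", calibrated" else ", raw"))
  invisible(x)
}

#' @export
dim.hyper_cube <- function(x) dim(x$values)

#' Dark/white reference pair for transmittance calibration
#'
#' References may be full cubes (same geometry as the raw cube) or
#' per-line 2-D arrays of shape `(cols, bands)`, which are broadcast along
#' the scan (row) axis during calibration — the natural shape for a
#' line-scan acquisition where one reference frame covers every scan line.
#'
#' @param dark,white numeric arrays of detector counts; both 2-D
#'   `(cols, bands)` or both 3-D `(rows, cols, bands)`.
#' @return an object of class `reference_pair`.
#' @export
reference_pair <- function(dark, white) {
  dark <- unclass(dark); white <- unclass(white)
  if (!identical(dim(dark), dim(white)))
    stop("dark and white references must have identical dimensions")
  nd <- length(dim(dark))
  if (!nd %in% c(2L, 3L))
    stop("references must be 2-D (cols, bands) or 3-D (rows, cols, bands)")
  frac_ok <- mean(white >= dark)
  if (frac_ok < 0.99)
    warning(sprintf(
      "white reference below dark on %.2f%% of elements; check acquisition",
      100 * (1 - frac_ok)))
  structure(list(dark = dark, white = white), class = "reference_pair")
}

#' Foreground mask separating sample pixels from background
#'
#' @param mask logical matrix, `TRUE` marking sample (ginseng) pixels.
#' @return an object of class `sample_mask` with the pixel count cached in
#'   `n_foreground`.
#' @export
sample_mask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix")
  structure(list(mask = mask, n_foreground = sum(mask)),
            class = "sample_mask")
}

#' @export
print.sample_mask <- function(x, ...) {
  cat(sprintf("<sample_mask> %d x %d, %d foreground pixels\n",
              nrow(x$mask), ncol(x$mask), x$n_foreground))
  invisible(x)
}

# internal: check a mask against a cube's spatial shape
check_mask_cube <- function(mask, cube) {
  if (!identical(dim(mask$mask), dim(cube$values)[1:2]))
    stop(sprintf("mask shape (%d x %d) does not match cube (%d x %d)",
                 nrow(mask$mask), ncol(mask$mask),
                 dim(cube$values)[1], dim(cube$values)[2]))
  invisible(TRUE)
}

# internal: index of the band center nearest a requested wavelength (nm)
nearest_band <- function(wavelengths, lambda) {
  if (lambda < min(wavelengths) || lambda > max(wavelengths))
    stop(sprintf(
      "wavelength %.1f nm outside axis [%.1f, %.1f]; nearest available bands: %.1f, %.1f",
      lambda, min(wavelengths), max(wavelengths),
      utils::head(wavelengths, 1), utils::tail(wavelengths, 1)))
  which.min(abs(wavelengths - lambda))
}
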