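#' Dark/white reference calibration of a raw transmittance cube
#'
#' Converts raw detector counts to transmittance pixelwise:
#' \deqn{X_C = (T^R - T^D) / (T^B - T^D)}
#' where \eqn{T^R} is the raw image, \eqn{T^D} the dark reference
#' (0% transmittance, lens capped) and \eqn{T^B} the white reference
#' (100% transmittance, bare glass plate). Per-line (2-D, `cols x bands`)
#' references are broadcast along the scan (row) axis.
#'
#' Pixels where the reference dynamic range `|white - dark|` falls below
#' `epsilon` cannot be calibrated; they are set to 0 and counted in
#' `meta$n_guarded` rather than propagating infinities.
#'
#' @param raw a raw [hyper_cube] of detector counts.
#' @param refs a [reference_pair].
#' @param epsilon guard threshold on the denominator; default
#'   `1e-6` of the white reference's dynamic range.
#' @return a calibrated [hyper_cube] (`meta$calibrated = TRUE`), values
#'   finite everywhere.
#' @export
calibrate <- function(raw, refs, epsilon = NULL) {
  stopifnot(inherits(raw, "hyper_cube"), inherits(refs, "reference_pair"))
  if (isTRUE(raw$meta$calibrated))
    warning("input cube is already flagged calibrated; calibrating again")
  d <- dim(raw$values)

  dark <- refs$dark; white <- refs$white
  if (length(dim(dark)) == 2L) {
    if (!identical(dim(dark), c(d[2], d[3])))
      stop(sprintf(
        "2-D reference geometry (%d x %d) does not match cube (cols=%d, bands=%d)",
        dim(dark)[1], dim(dark)[2], d[2], d[3]))
    dark  <- broadcast_ref(dark, d)
    white <- broadcast_ref(white, d)
  } else if (!identical(dim(dark), d)) {
    stop(sprintf("3-D reference geometry (%s) does not match cube (%s)",
                 paste(dim(dark), collapse = "x"), paste(d, collapse = "x")))
  }

  if (is.null(epsilon)) {
    dr <- diff(range(white))
    epsilon <- 1e-6 * if (dr > 0) dr else max(abs(white), 1)
  }
  stopifnot(epsilon > 0)

  den <- white - dark
  guard <- abs(den) < epsilon
  out <- (raw$values - dark) / den
  out[guard] <- 0
  meta <- raw$meta
  meta$calibrated <- TRUE
  meta$n_guarded <- sum(guard)
  hyper_cube(out, raw$wavelengths, meta)
}

#' Expand a per-line reference frame to full cube geometry
#'
#' Replicates a `(cols, bands)` reference frame of a line-scan
#' acquisition along the scan (row) axis, yielding a `(rows, cols,
#' bands)` array.
#'
#' @param ref numeric matrix `(cols, bands)`.
#' @param d target cube dimensions `c(rows, cols, bands)`.
#' @return a 3-D array.
#' @export
broadcast_ref <- function(ref, d) {
  out <- array(0, d)
  for (b in seq_len(d[3]))
    out[, , b] <- matrix(ref[, b], nrow = d[1], ncol = d[2], byrow = TRUE)
  out
}

#' Segment the sample from the bright background
#'
#' On a calibrated cube the glass-plate background transmits near 1 while
#' the root attenuates, so foreground is defined as pixels whose
#' band-averaged transmittance falls below `threshold`. Speckle is removed
#' by keeping only the largest connected foreground component
#' (8-connectivity).
#'
#' @param cube a calibrated [hyper_cube].
#' @param threshold band-averaged transmittance cut, in (0, 1).
#'   Default 0.85.
#' @return a [sample_mask].
#' @export
segment_background <- function(cube, threshold = 0.85) {
  stopifnot(inherits(cube, "hyper_cube"), threshold > 0, threshold < 1)
  if (!isTRUE(cube$meta$calibrated))
    warning("segmenting an uncalibrated cube; background may not be near 1")
  d <- dim(cube$values)
  avg <- matrix(rowMeans(matrix(cube$values, nrow = d[1] * d[2])),
                nrow = d[1], ncol = d[2])
  fg <- avg < threshold
  if (!any(fg))
    stop(sprintf("no sample detected at threshold %g", threshold))
  sample_mask(largest_component(fg))
}

# keep the largest 8-connected TRUE component of a logical matrix
largest_component <- function(fg) {
  lab <- EBImage::bwlabel(fg)
  tab <- tabulate(lab[lab > 0])
  fg & (lab == which.max(tab))
}
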