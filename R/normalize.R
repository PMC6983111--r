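#' Per-pixel spectrum normalization
#'
#' Rescales each foreground pixel's spectrum independently, removing
#' path-length/thickness variation (roots are 15-20 mm thick, so absolute
#' transmittance varies strongly pixel to pixel). Three methods:
#' \describe{
#'   \item{range}{\eqn{(x - \min x) / (\max x - \min x)}; output in
#'     \[0, 1\] per spectrum. The default.}
#'   \item{max}{\eqn{x / \max x}; per-spectrum maximum becomes 1.}
#'   \item{mean}{\eqn{x / \mathrm{mean}\, x}; per-spectrum mean becomes 1.}
#' }
#' Background pixels are left untouched. Degenerate spectra (zero range,
#' or non-positive max/mean for the ratio methods) are set to all-zeros
#' and counted in `meta$n_degenerate`; if more than 5% of the foreground
#' is degenerate the call errors, since that indicates a systematic
#' acquisition failure rather than a few dead pixels.
#'
#' @param cube a calibrated [hyper_cube].
#' @param mask a [sample_mask].
#' @param method `"range"` (default), `"max"`, or `"mean"`.
#' @return a [hyper_cube] with normalized foreground spectra;
#'   `meta$normalization` records the method.
#' @export
normalize_cube <- function(cube, mask, method = c("range", "max", "mean")) {
  stopifnot(inherits(cube, "hyper_cube"), inherits(mask, "sample_mask"))
  method <- match.arg(method)
  check_mask_cube(mask, cube)

  d <- dim(cube$values)
  flat <- matrix(cube$values, nrow = d[1] * d[2])  # pixels x bands
  fg <- which(as.vector(mask$mask))
  X <- flat[fg, , drop = FALSE]

  if (method == "range") {
    lo <- apply(X, 1, min); hi <- apply(X, 1, max)
    degen <- (hi - lo) <= 0
    Xn <- (X - lo) / (hi - lo)
  } else if (method == "max") {
    hi <- apply(X, 1, max)
    degen <- hi <= 0
    Xn <- X / hi
  } else {
    mu <- rowMeans(X)
    degen <- mu <= 0
    Xn <- X / mu
  }
  Xn[degen, ] <- 0

  n_deg <- sum(degen)
  if (n_deg > 0.05 * length(fg))
    stop(sprintf("%d of %d foreground spectra (%.1f%%) are degenerate under %s normalization",
                 n_deg, length(fg), 100 * n_deg / length(fg), method))

  flat[fg, ] <- Xn
  meta <- cube$meta
  meta$normalization <- method
  meta$n_degenerate <- n_deg
  hyper_cube(array(flat, d), cube$wavelengths, meta)
}
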