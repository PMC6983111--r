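#' Detection configuration for two-band ratio segmentation
#'
#' Holds the waveband pair, threshold, and speckle filter controlling
#' whitening detection. Defaults follow the characteristic-band analysis:
#' the ratio of the 950 nm image to the 1326 nm image, binarized at
#' threshold 5 (chosen from the 3-D mesh-plot diagnostic, where whitened
#' pixel intensities sit above 5), with connected regions smaller than 5
#' pixels discarded as speckle.
#'
#' @param lambda_num,lambda_den numerator/denominator wavelengths (nm).
#' @param threshold binarization threshold `T` (> 0); a ratio pixel is
#'   whitening iff `ratio >= T`.
#' @param min_region_pixels smallest connected whitening region kept;
#'   0 disables the speckle filter.
#' @param epsilon denominator guard for the ratio.
#' @return an object of class `detection_config`.
#' @export
detection_config <- function(lambda_num = 950, lambda_den = 1326,
                             threshold = 5, min_region_pixels = 5L,
                             epsilon = 1e-6) {
  if (lambda_num == lambda_den)
    stop("numerator and denominator wavelengths must differ")
  if (threshold <= 0) stop("threshold must be > 0")
  structure(list(lambda_num = lambda_num, lambda_den = lambda_den,
                 threshold = threshold,
                 min_region_pixels = as.integer(min_region_pixels),
                 epsilon = epsilon),
            class = "detection_config")
}

#' Two-band ratio image
#'
#' Divides the single-band image nearest `lambda_num` by the one nearest
#' `lambda_den`, per foreground pixel. The ratio cancels per-pixel
#' path-length (thickness) effects — any positive scaling of a pixel's
#' whole spectrum leaves it unchanged — while preserving the spectral
#' contrast between whitened and healthy tissue. Computed on calibrated
#' transmittance (not per-spectrum-normalized data, which would destroy
#' the absolute contrast the fixed threshold relies on).
#'
#' @param cube a calibrated [hyper_cube].
#' @param mask a [sample_mask].
#' @param config a [detection_config].
#' @return numeric matrix; foreground holds the ratio, background and
#'   guarded pixels hold `NA`. Attributes `band_num_nm` / `band_den_nm`
#'   record the band centers actually used and `n_excluded` the pixels
#'   dropped for a near-zero denominator.
#' @export
ratio_image <- function(cube, mask, config = detection_config()) {
  stopifnot(inherits(cube, "hyper_cube"), inherits(mask, "sample_mask"),
            inherits(config, "detection_config"))
  check_mask_cube(mask, cube)
  if (!isTRUE(cube$meta$calibrated))
    warning("ratio image on an uncalibrated cube")
  b_num <- nearest_band(cube$wavelengths, config$lambda_num)
  b_den <- nearest_band(cube$wavelengths, config$lambda_den)
  num <- cube$values[, , b_num]
  den <- cube$values[, , b_den]
  out <- matrix(NA_real_, nrow(num), ncol(num))
  ok <- mask$mask & abs(den) >= config$epsilon
  out[ok] <- num[ok] / den[ok]
  structure(out,
            band_num_nm = cube$wavelengths[b_num],
            band_den_nm = cube$wavelengths[b_den],
            n_excluded = sum(mask$mask) - sum(ok))
}

#' Threshold a ratio image into a binary whitening map
#'
#' Foreground pixels with ratio at or above the threshold (inclusive
#' `>=`) become 1 (whitening), everything else 0. Connected whitening
#' regions smaller than `min_region_pixels` are removed as speckle.
#'
#' @param image ratio image from [ratio_image()].
#' @param mask the matching [sample_mask].
#' @param config a [detection_config].
#' @return integer 0/1 matrix the same shape as the image.
#' @export
threshold_binary <- function(image, mask, config = detection_config()) {
  stopifnot(inherits(mask, "sample_mask"))
  if (!identical(dim(image), dim(mask$mask)))
    stop("ratio image and mask are not aligned")
  bin <- mask$mask & !is.na(image) & image >= config$threshold
  if (config$min_region_pixels > 1L && any(bin)) {
    lab <- EBImage::bwlabel(bin)
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes < config$min_region_pixels)
    bin[lab %in% small] <- FALSE
  }
  matrix(as.integer(bin), nrow(image), ncol(image))
}

#' Percent-whitening statistic for one sample
#'
#' Counts whitening pixels `Wp` and healthy pixels `Hp` over the sample
#' foreground, with `Tp = Wp + Hp` the total sample pixels, and reports
#' \deqn{P_{wp} = 100 \cdot W_p / T_p} — the percentage of the root's
#' cross-section flagged as whitened.
#'
#' @param binary 0/1 whitening map from [threshold_binary()]; its 1s must
#'   lie inside the mask.
#' @param mask the [sample_mask].
#' @return an object of class `whitening_report`: integers `Wp`, `Hp`,
#'   `Tp` and percentage `Pwp`.
#' @export
whitening_percentage <- function(binary, mask) {
  stopifnot(inherits(mask, "sample_mask"))
  if (mask$n_foreground == 0L) stop("empty sample mask")
  if (!identical(dim(binary), dim(mask$mask)))
    stop("binary map and mask are not aligned")
  if (any(binary == 1L & !mask$mask))
    stop("binary whitening map marks pixels outside the sample mask")
  Wp <- sum(binary == 1L)
  Tp <- mask$n_foreground
  Hp <- Tp - Wp
  structure(list(Wp = Wp, Hp = Hp, Tp = Tp, Pwp = 100 * Wp / Tp,
                 outlier_flag = NA),
            class = "whitening_report")
}

#' @export
print.whitening_report <- function(x, ...) {
  cat(sprintf("<whitening_report> Wp=%d Hp=%d Tp=%d Pwp=%.2f%%%s\n",
              x$Wp, x$Hp, x$Tp, x$Pwp,
              if (isTRUE(x$outlier_flag)) " (3-sigma outlier)" else ""))
  invisible(x)
}

#' Three-sigma outlier screen across samples
#'
#' Flags any percent-whitening value farther than three standard
#' deviations from the mean of all values (single pass; mean and sd are
#' not recomputed after removing flagged values).
#'
#' @param values numeric vector of `Pwp` values, length >= 3.
#' @return logical vector of flags, same length as `values`.
#' @export
sigma3_screen <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L)
    stop("3-sigma screen needs at least 3 values")
  s <- stats::sd(values)
  if (s == 0) return(rep(FALSE, length(values)))
  abs(values - mean(values)) > 3 * s
}

#' Export ratio-image pixels for 3-D mesh-plot diagnostics
#'
#' Flattens a ratio image into `(x, y, intensity)` records suitable for a
#' surface/mesh plot of pixel intensity — the diagnostic used to choose
#' the binarization threshold (whitened pixel intensities form the upper
#' mode of the surface). Background pixels are kept as missing-intensity
#' records so the grid stays rectangular.
#'
#' @param image ratio image.
#' @param mask optional [sample_mask]; pixels outside it get `NA`
#'   intensity.
#' @return data.frame with columns `x` (col), `y` (row), `intensity`.
#' @export
mesh_plot_data <- function(image, mask = NULL) {
  stopifnot(is.matrix(image))
  inten <- image
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "sample_mask"))
    if (!identical(dim(image), dim(mask$mask)))
      stop("image and mask are not aligned")
    inten[!mask$mask] <- NA_real_
  }
  grid <- expand.grid(y = seq_len(nrow(image)), x = seq_len(ncol(image)))
  data.frame(x = grid$x, y = grid$y,
             intensity = inten[cbind(grid$y, grid$x)])
}
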