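#' Parametric specification of a synthetic ginseng phantom
#'
#' Describes a simulated line-scan transmittance acquisition of one root:
#' an elliptical sample silhouette on a bright glass-plate background,
#' smooth transmittance spectra with absorption dips at the ginsenoside-
#' associated bands (950, 1110, 1326 nm), and — for abnormal phantoms — a
#' centered elliptical whitened region of known area fraction whose
#' optically denser tissue attenuates transmittance over 900-1050 nm and
#' 1150-1400 nm and deepens the 950/1326 nm absorption features.
#'
#' The default geometry is half the instrument's 320 x 500 spatial
#' resolution, keeping a full phantom cheap to simulate while exercising
#' every pipeline stage; full resolution is one argument away.
#'
#' @param spatial_shape `c(rows, cols)` of the simulated scan.
#' @param wavelengths band-center grid (nm); default 168 bands spanning
#'   900-1700 nm (~4.8 nm spacing), matching a Pika NIR-320-class camera.
#' @param sample_center,sample_axes ellipse center and semi-axes (pixels)
#'   of the root silhouette; defaults fill most of the frame.
#' @param whitening_fraction target whitened area as a fraction of the
#'   sample area, in `[0, 1)`; 0 means a normal root.
#' @param whitening_center center of the whitened ellipse (defaults to
#'   the sample center — whitening occurs in the central tissue).
#' @param baseline_level,baseline_slope linear baseline transmittance
#'   `level - slope * (lambda - 900)/800`.
#' @param dip_centers,dip_depths,dip_widths Gaussian absorption features
#'   (nm, transmittance units, nm) shared by both tissue classes.
#' @param water_band the broad 1450 nm water absorption
#'   (`list(center, depth, width)`), shared by both classes; it anchors
#'   the common minimum that per-spectrum range normalization pins to 0.
#' @param whitening_windows 2 x 2 matrix of attenuation windows (nm);
#'   whitening reduces transmittance inside these.
#' @param whitening_centers center (nm) of the attenuation within each
#'   window — the characteristic band the disorder is read from.
#' @param whitening_sigma Gaussian width (nm) of each window's
#'   attenuation; defaults keep the loss essentially inside its window.
#' @param whitening_attenuation peak fractional transmittance loss per
#'   window, each in (0, 1]: whitened tissue is multiplied by
#'   `1 - A * exp(-(lambda - center)^2 / (2 sigma^2))`.
#' @param whitening_dip_boost extra narrow absorption depth added, in
#'   whitened tissue, at the first and third dip centers (950 and
#'   1326 nm) — the deepened ginsenoside features of denser tissue.
#' @param noise_sd relative (multiplicative) Gaussian noise on sample
#'   pixel spectra; default 1%.
#' @param dark_level,white_level detector counts of the dark offset and
#'   the unobstructed white reference.
#' @param seed integer RNG seed for [generate_cube()].
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(spatial_shape = c(160L, 250L),
                         wavelengths = seq(900, 1700, length.out = 168),
                         sample_center = NULL,
                         sample_axes = NULL,
                         whitening_fraction = 0,
                         whitening_center = NULL,
                         baseline_level = 0.84,
                         baseline_slope = 0.06,
                         dip_centers = c(950, 1110, 1326),
                         dip_depths = c(0.03, 0.025, 0.01),
                         dip_widths = c(16, 20, 16),
                         water_band = list(center = 1450, depth = 0.40,
                                           width = 45),
                         whitening_windows = rbind(c(900, 1050),
                                                   c(1150, 1400)),
                         whitening_centers = c(950, 1326),
                         whitening_sigma = c(45, 75),
                         whitening_attenuation = c(0.50, 0.80),
                         whitening_dip_boost = c(0.05, 0.12),
                         noise_sd = 0.01,
                         dark_level = 100,
                         white_level = 4000,
                         seed = 1L) {
  spatial_shape <- as.integer(spatial_shape)
  if (is.null(sample_center)) sample_center <- (spatial_shape + 1) / 2
  if (is.null(sample_axes))
    sample_axes <- c(0.38, 0.44) * spatial_shape
  if (is.null(whitening_center)) whitening_center <- sample_center
  if (whitening_fraction < 0 || whitening_fraction >= 1)
    stop("whitening_fraction must be in [0, 1)")
  if (any(whitening_attenuation <= 0) || any(whitening_attenuation > 1))
    stop("whitening_attenuation factors must be in (0, 1]")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  spec <- structure(list(
    spatial_shape = spatial_shape, wavelengths = as.numeric(wavelengths),
    sample_center = sample_center, sample_axes = sample_axes,
    whitening_fraction = whitening_fraction,
    whitening_center = whitening_center,
    baseline_level = baseline_level, baseline_slope = baseline_slope,
    dip_centers = dip_centers, dip_depths = dip_depths,
    dip_widths = dip_widths, water_band = water_band,
    whitening_windows = whitening_windows,
    whitening_centers = whitening_centers,
    whitening_sigma = whitening_sigma,
    whitening_attenuation = whitening_attenuation,
    whitening_dip_boost = whitening_dip_boost,
    noise_sd = noise_sd, dark_level = dark_level,
    white_level = white_level, seed = as.integer(seed)),
    class = "phantom_spec")
  # noiseless spectra must be valid transmittances before clipping
  for (w in c(FALSE, TRUE)) {
    s <- generate_spectrum(spec, whitened = w, clip = FALSE)
    if (any(s <= 0) || any(s > 1))
      stop("spectral parameters give transmittance outside (0, 1]")
  }
  spec
}

#' Noiseless transmittance spectrum of phantom tissue
#'
#' Smooth baseline minus Gaussian absorption dips (950/1110/1326 nm
#' features plus the broad 1450 nm water band). Whitened tissue is
#' additionally attenuated by Gaussian optical-density bumps centered on
#' the characteristic bands of the two whitening windows (900-1050 and
#' 1150-1400 nm) and has deepened 950/1326 nm features — the spectral
#' signature of optically dense whitened material.
#'
#' @param spec a [phantom_spec].
#' @param whitened logical; generate whitened-tissue spectrum?
#' @param clip clip the result into (0, 1]? (`FALSE` is used internally
#'   to validate that the model itself stays in range.)
#' @return numeric transmittance vector over `spec$wavelengths`, clipped
#'   to (0, 1].
#' @export
generate_spectrum <- function(spec, whitened = FALSE, clip = TRUE) {
  wl <- spec$wavelengths
  u <- (wl - 900) / 800
  s <- spec$baseline_level - spec$baseline_slope * u
  for (i in seq_along(spec$dip_centers))
    s <- s - spec$dip_depths[i] *
      exp(-0.5 * ((wl - spec$dip_centers[i]) / spec$dip_widths[i])^2)
  wb <- spec$water_band
  s <- s - wb$depth * exp(-0.5 * ((wl - wb$center) / wb$width)^2)
  if (whitened) {
    att <- rep(1, length(wl))
    for (w in seq_along(spec$whitening_centers))
      att <- att * (1 - spec$whitening_attenuation[w] *
        exp(-0.5 * ((wl - spec$whitening_centers[w]) /
                    spec$whitening_sigma[w])^2))
    s <- s * att
    boosts <- c(1L, 3L)  # 950 and 1326 nm features
    for (j in seq_along(boosts)) {
      i <- boosts[j]
      s <- s - spec$whitening_dip_boost[j] *
        exp(-0.5 * ((wl - spec$dip_centers[i]) / spec$dip_widths[i])^2)
    }
  }
  if (clip) pmin(pmax(s, 1e-4), 1) else s
}

#' Simulate a raw acquisition of one phantom
#'
#' Renders the phantom as raw detector counts: background pixels carry
#' the white-reference counts exactly (bare glass plate), sample pixels
#' carry `spectrum * (white - dark) + dark` with multiplicative Gaussian
#' noise on the spectrum. The white reference has a smooth quadratic
#' illumination profile across the line axis and the dark reference a
#' small per-band ramp, so calibration has real work to do. References
#' are returned noiseless as per-line `(cols, bands)` frames.
#'
#' The whitened ellipse's semi-axes are solved so that the rasterized
#' whitened-pixel count matches the target fraction as closely as
#' pixelation allows; the achieved fraction is recorded in the ground
#' truth.
#'
#' @param spec a [phantom_spec].
#' @return list with `raw` (a raw [hyper_cube]), `refs` (a
#'   [reference_pair]), and `truth` — list of `sample` (logical matrix),
#'   `whitening` (logical matrix), `target_fraction`, `actual_fraction`.
#' @export
generate_cube <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- c(spec$spatial_shape, length(spec$wavelengths))
  rows <- d[1]; cols <- d[2]; bands <- d[3]

  smask <- ellipse_mask(rows, cols, spec$sample_center, spec$sample_axes)
  n_samp <- sum(smask)
  if (n_samp == 0L) stop("sample ellipse contains no pixels")

  wmask <- matrix(FALSE, rows, cols)
  actual_fraction <- 0
  if (spec$whitening_fraction > 0) {
    target_n <- round(spec$whitening_fraction * n_samp)
    scale <- solve_ellipse_scale(rows, cols, spec$whitening_center,
                                 spec$sample_axes, target_n)
    wmask <- ellipse_mask(rows, cols, spec$whitening_center,
                          spec$sample_axes * scale)
    if (any(wmask & !smask))
      stop("whitening ellipse extends outside the sample ellipse")
    actual_fraction <- sum(wmask) / n_samp
  }

  # references: illumination profile across the line (column) axis,
  # small dark-current ramp across bands
  illum <- 1 - 0.15 * ((seq_len(cols) - (cols + 1) / 2) / (cols / 2))^2
  white_cb <- outer(illum, rep(spec$white_level, bands))
  dark_cb <- outer(rep(1, cols), spec$dark_level + 0.02 * (seq_len(bands) - 1))

  sp_normal <- generate_spectrum(spec, whitened = FALSE)
  sp_white <- generate_spectrum(spec, whitened = TRUE)

  fg <- which(smask)                        # column-major linear indices
  fg_rc <- which(smask, arr.ind = TRUE)
  is_w <- wmask[fg]
  base <- matrix(0, length(fg), bands)
  if (any(!is_w))
    base[!is_w, ] <- matrix(sp_normal, sum(!is_w), bands, byrow = TRUE)
  if (any(is_w))
    base[is_w, ] <- matrix(sp_white, sum(is_w), bands, byrow = TRUE)
  noise <- matrix(stats::rnorm(length(fg) * bands, 0, spec$noise_sd),
                  length(fg), bands)
  base <- base * (1 + noise)

  raw <- array(0, d)
  for (b in seq_len(bands)) {
    plane <- matrix(white_cb[, b], rows, cols, byrow = TRUE)
    w_fg <- white_cb[fg_rc[, 2], b]
    d_fg <- dark_cb[fg_rc[, 2], b]
    plane[fg] <- base[, b] * (w_fg - d_fg) + d_fg
    raw[, , b] <- plane
  }

  list(raw = hyper_cube(raw, spec$wavelengths,
                        meta = list(calibrated = FALSE,
                                    phantom_seed = spec$seed)),
       refs = reference_pair(dark_cb, white_cb),
       truth = list(sample = smask, whitening = wmask,
                    target_fraction = spec$whitening_fraction,
                    actual_fraction = actual_fraction))
}

# logical ellipse rasterization; center/axes in (row, col) pixels
ellipse_mask <- function(rows, cols, center, axes) {
  r <- matrix(seq_len(rows), rows, cols)
  c <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  ((r - center[1]) / axes[1])^2 + ((c - center[2]) / axes[2])^2 <= 1
}

# find the axis scale whose rasterized ellipse has ~target_n pixels
solve_ellipse_scale <- function(rows, cols, center, axes, target_n) {
  count <- function(s) sum(ellipse_mask(rows, cols, center, axes * s))
  lo <- 0.01; hi <- 1
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (count(mid) < target_n) lo <- mid else hi <- mid
  }
  # pick the closer of the bracketing scales
  if (abs(count(lo) - target_n) < abs(count(hi) - target_n)) lo else hi
}

#' Frozen phantom fixtures used throughout tests and analyses
#'
#' A named set of [phantom_spec]s: three abnormal fixtures matching the
#' reference sliced-root severities (S1 48.18%, S3 53.14%, S4 37.66%
#' whitened area), two normal roots, and a {10, 25, 50}% severity sweep.
#' Spectral parameters are frozen so that, under the default
#' [detection_config()], whitened pixels' 950/1326 ratio exceeds the
#' threshold of 5 and normal pixels' does not.
#'
#' @return named list of [phantom_spec] objects.
#' @export
fixture_library <- function() {
  list(
    S1       = phantom_spec(whitening_fraction = 0.4818, seed = 101L),
    S3       = phantom_spec(whitening_fraction = 0.5314, seed = 103L),
    S4       = phantom_spec(whitening_fraction = 0.3766, seed = 104L),
    normal_1 = phantom_spec(whitening_fraction = 0,      seed = 201L),
    normal_2 = phantom_spec(whitening_fraction = 0,      seed = 202L),
    sweep_10 = phantom_spec(whitening_fraction = 0.10,   seed = 301L),
    sweep_25 = phantom_spec(whitening_fraction = 0.25,   seed = 302L),
    sweep_50 = phantom_spec(whitening_fraction = 0.50,   seed = 303L))
}
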