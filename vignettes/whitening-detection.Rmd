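---
title: "Detecting inner whitening in ginseng roots from NIR transmittance hypercubes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting inner whitening in ginseng roots from NIR transmittance hypercubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Inner whitening is an internal disorder of ginseng (*Panax ginseng*)
roots: central tissue turns whitish and optically dense while the root
looks normal from outside. Because whitened roots are downgraded,
grading requires an internal inspection, traditionally done by a human
holding each root against a light source. Near-infrared (900–1700 nm)
*transmittance* imaging sees through the root: a line-scan camera
records a hypercube — two spatial axes plus a spectral axis — in which
whitened tissue transmits less light than healthy tissue, most visibly
over 900–1050 nm and 1150–1400 nm.

`whitenir` implements the full processing chain from raw counts to a
per-root severity percentage, and a phantom generator that plants
whitened regions of known size so the chain can be validated without an
instrument.

## Pipeline and model

The stage order is: calibrate → mask → (normalize →) PCA/waveband
selection → two-band ratio → threshold → percent whitening.

**Calibration.** Raw counts become transmittance through dark/white
referencing,

$$X_C = \frac{T^R - T^D}{T^B - T^D},$$

with $T^D$ acquired lens-capped (0 % transmittance) and $T^B$ through
the bare glass plate (100 %). Pixels whose reference dynamic range
$|T^B - T^D|$ falls below an epsilon (default $10^{-6}$ of the white
reference's dynamic range) cannot be calibrated; they are set to 0 and
counted rather than left infinite. References may be full cubes or
single `(cols × bands)` frames; a frame is broadcast along the scan
axis, the natural model for a line-scan system where one reference
exposure covers every line. Whether real acquisitions average several
reference frames is immaterial here: the generator returns noiseless
references, and `calibrate()` accepts either form.

**Background masking.** On a calibrated cube the glass plate transmits
≈ 1, so foreground is `band-averaged transmittance < threshold`. The
threshold default is 0.85 — high enough to catch pale healthy tissue,
far enough from 1 to reject the plate — and configurable, since it is an
instrument-dependent quantity. Only the largest connected component is
kept; stray specks from dust or noise are not samples.

**Normalization.** Root thickness (15–20 mm) varies within and between
samples, scaling whole-pixel spectra. Per-pixel-spectrum normalization
removes this: `range` maps each spectrum to $[0,1]$
($(x-\min x)/(\max x-\min x)$), `max` and `mean` divide by the
respective statistic. The scope is per pixel spectrum — a global scaling
would leave the thickness variation in place, which is the variation the
step exists to remove. `range` is the default; all three are exposed.
Degenerate spectra (zero range, non-positive max/mean) become all-zeros
and are counted; the run only aborts if more than 5 % of the foreground
degenerates, which indicates systematic failure rather than dead pixels.

**PCA and waveband selection.** The masked cube is unfolded to a
pixels × bands matrix (row-major within each sample) and decomposed as
$X = T P^{\mathsf T} + E$ after mean-centering. No variance scaling is
applied: the bands share units, and correlation-mode PCA would distort
the loadings that band selection reads. Eigenvector sign is fixed by
making each loading's largest-magnitude element positive, so score
images have reproducible polarity. `select_wavebands()` returns the
wavelengths of the largest-|loading| *local extrema* (strictly greater
than both neighbors; a plateau counts once at its first band; ties break
toward the lower wavelength). Which component discriminates whitened
from healthy tissue is a property of the data set, not the algorithm, so
the component index is an argument (with 2 as the conventional default)
and `rank_components()` — standardized difference of per-sample mean
scores between groups — is provided as the analyst's aid. On the phantom
ensemble the discriminating component is the first; on instrument data
with stronger between-root variation it is typically a later one.

**Per-band ANOVA.** A one-way fixed-effects ANOVA
($F = \mathrm{MSB}/\mathrm{MSW}$, df $(k-1, N-k)$) compares groups band
by band. The observation unit is one *per-root mean foreground
spectrum*: pixels within a root are strongly correlated, so treating
them as observations would inflate $F$ by orders of magnitude. Zero
within-group variance with unequal means reports $F=\infty, p=0$;
identical constant groups report $F=0, p=1$.

**Ratio image, threshold, severity.** The detection path divides the
image at 950 nm by the image at 1326 nm (nearest band centers; the
centers actually used are recorded). The ratio is invariant under
per-pixel scaling of the spectrum — thickness cancels — while whitened
tissue, attenuated much more strongly near 1326 nm than near 950 nm,
stands out. The ratio is computed on *calibrated* transmittance, not on
range-normalized spectra: normalization rescales every spectrum into
$[0,1]$ and destroys the absolute contrast a fixed threshold relies on.
Binarization is inclusive, $g = 1 \iff f \ge T$, with $T = 5$ by
default — on the 3-D mesh-plot diagnostic (`mesh_plot_data()`) whitened
pixel intensities form the upper mode, above 5, and healthy tissue the
lower mode, below it. Connected whitening regions smaller than 5 pixels
are discarded as speckle (set `min_region_pixels = 0` to disable).
Severity is

$$T_p = W_p + H_p, \qquad P_{wp} = 100\,W_p/T_p,$$

exact integer counting over the sample mask. Across samples, a single-
pass 3σ screen flags $|P_{wp} - \bar P| > 3\,\mathrm{sd}$; the whole-run
summary labels a root abnormal when $P_{wp}$ exceeds a configurable 5 %
cutoff (inspection-based grading gives no numeric rule, so the cutoff is
explicit and saved with the run configuration).

## The phantom generator

`phantom_spec()`/`generate_cube()` emulate one line-scan acquisition:

- an elliptical root silhouette on a bright glass-plate background
  (background pixels carry the white-reference counts exactly);
- a white reference with a smooth quadratic illumination profile across
  the line axis and a dark reference with a small per-band ramp, so
  calibration has real non-uniformity to remove;
- smooth tissue spectra: linear baseline minus Gaussian absorption
  features at 950, 1110 and 1326 nm (the ginsenoside-associated bands)
  and the broad 1450 nm water band;
- whitened tissue: transmittance multiplied by Gaussian optical-density
  bumps centered at 950 nm (σ 45 nm, peak loss 0.50) and 1326 nm (σ
  75 nm, peak loss 0.80) — the attenuation lives inside the 900–1050 and
  1150–1400 nm windows — plus deepened narrow 950/1326 nm features
  (0.05/0.12);
- a centered whitened ellipse whose axes are solved so the rasterized
  pixel count matches the target area fraction (achieved fractions land
  within ~0.01 pp of target; both are recorded);
- 1 % relative Gaussian noise on sample-pixel spectra, multiplicative,
  mimicking shot-dominated transmittance noise.

Two shape choices deserve a note. The attenuation is Gaussian-shaped
around each window's characteristic band rather than flat across the
window: a flat profile spreads the class difference uniformly over the
window, and the discriminating loading then peaks mid-window instead of
at the planted features — defeating the generator's purpose of testing
band *recovery*. The shared water band anchors each spectrum's minimum
away from the whitening bands, so range normalization (which pins the
per-spectrum minimum to 0) retains the class contrast at 1326 nm. These
parameters are frozen: under the default detection configuration,
whitened pixels' ratio is ≈ 9.4 and healthy pixels' ≈ 1.0, on either
side of the threshold 5.

Severity fixtures `S1/S3/S4` plant 48.18 / 53.14 / 37.66 % whitened
area — the severities of the reference sliced-root set — alongside two
normal roots and a 10/25/50 % sweep. Whitening is binary (a pixel is
whitened or not) because the detection output is binary; real disorder
severity is graded continuously, which the generator does not model.
Other unmodeled features of real data: irregular root outlines and
protrusions, graded whitening boundaries, scattering gradients,
stray-light and detector nonlinearity. Passing tests therefore
demonstrate that the *chain of operations* is correct and recovers known
ground truth, not that the fixed threshold 5 transfers to any particular
instrument.

## Problem sizes and runtime choices

The default phantom frame is 160 × 250 × 168 — half the spatial
resolution of the 320 × 500 reference geometry, full spectral
resolution — which keeps one fixture's simulate-to-report run at a few
seconds; full resolution is `spatial_shape = c(320, 500)` away. The
PCA ensemble (6 normal + 6 abnormal) uses 80 × 125 frames, about 63 000
foreground spectra, ample for a 3-component fit. The band grid
`seq(900, 1700, length.out = 168)` has 4.79 nm spacing, so requested
wavelengths are mapped to nearest band centers (950 → 947.9, 1326 →
1326.3) and those centers are reported.

## Numerical conventions

- Indexing is 1-based `(row, col)`, rows are the scan axis; unfolding is
  row-major within each sample and exactly invertible via the stored
  `(sample, row, col)` index.
- ENVI I/O supports BSQ/BIL/BIP interleaves, float32/float64, both byte
  orders; cubes are written float64 so round-trips are bit-identical.
- The calibration epsilon guard, the ratio's denominator epsilon, and
  the 5 % degenerate-spectrum budget are all configurable; defaults are
  stated above.
- `report.csv` numbers are written with fixed formatting so identical
  seed + configuration reproduce byte-identical reports.

## Limitations

The phantom is phenomenological, not radiative transfer: no layered
tissue optics, no illumination modeling beyond a smooth profile, no
instrument PSF. The threshold 5 and the 950/1326 nm pair are properties
of the reference system; for a new instrument the mesh-plot diagnostic
and the PCA/ANOVA path are the tools to re-derive them, and both are
exposed for exactly that reason.
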