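---
title: "Sparse O-PTIR reconstruction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse O-PTIR reconstruction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparseptir)
```

## The problem

Optical photothermal infrared (O-PTIR) microscopy measures mid-IR
absorbance with sub-micron (0.5 µm) spatial resolution, but it raster-scans:
acquisition time is proportional to the number of scanned rows (the slow y
axis) times the number of spectral bands. A discrete-frequency protocol with
28 fingerprint-region bands at full resolution is impractically slow for
whole tissue-microarray cores.

`sparseptir` implements a sparse acquisition-and-reconstruction scheme: one
band — Amide I at 1660 cm⁻¹, where protein absorbance is strong and spatial
structure is rich — is acquired at full resolution, while the remaining 27
bands keep only every *s*-th row (`s = dy_lo / dy_hi`, the decimation
factor). At the recommended operating point of 0.5 µm × 5 µm (`s = 10`) only
10% of the pixels of each non-reference band are measured, and the
row-proportional time model gives roughly a 7.6× reduction in scan time for
a 28-band stack, since

$$T = t_\text{row}\,\bigl(R + (B-1)\,\lceil R/s\rceil\bigr),$$

with `R` full-resolution rows, `B` bands and `t_row` the per-row scan time
(`acquisition_time_estimate()`). The missing rows are restored in two
stages.

### Stage 1: Fourier zero-pad interpolation (`fft_upsample_y()`)

Each decimated band is upsampled column by column: FFT along y, center the
spectrum, zero-pad symmetrically to the reference band's row count,
multiply by a Gaussian frequency window, inverse FFT, rescale by
`rows_hi / rows_lo`, take the real part. Choices that matter:

* **Window.** The Gaussian window `w(k) = exp(-k²/2σ²)` has unit gain at DC
  and reaches gain 0.5 at `window_half_gain_fraction × rows_lo/2`, i.e. at a
  fixed fraction of the *low-resolution* Nyquist index (default fraction 1).
  Anchoring σ to the actual sampling rate makes the amount of smoothing
  independent of the upsampling target. `Inf` disables the window; the
  window is applied to the full padded spectrum (the padded region is zero
  anyway, so this choice only shapes the retained band).
* **Windowing is y-only.** The x axis is sampled at full resolution;
  windowing it would discard measured detail.
* **Amplitude normalization** `rows_hi / rows_lo` preserves the mean
  absorbance of every band exactly, keeping spectra quantitative.
* **Nyquist handling.** For even `rows_lo` the Nyquist bin is split half and
  half into the ±Nyquist positions of the padded spectrum, so real images
  map to real images; the residual imaginary part is asserted below 1e-8 of
  the signal.

With these conventions, factor-1 upsampling is the identity to 1e-10,
constants are preserved exactly at any target size, and band-limited
signals are reproduced at the trigonometric interpolant (verified against
an independent DFT-sum oracle in the tests).

### Stage 2: curvelet-domain fusion (`sharpen_band()`, `reconstruct_cube()`)

Interpolation cannot restore y frequencies above the decimated Nyquist;
edges stay blurred. The fusion step borrows those frequencies from the
full-resolution reference band:

1. **Affine equalization** (`affine_equalize()`): per band, least-squares
   gain/offset `(a, b)` mapping the reference onto the band's intensity
   scale. This preserves each band's radiometry when reference detail is
   injected, and adjusts for absorption differences between bands. A
   constant reference degenerates to `a = 0, b = mean(band)`.
2. **Curvelet split**: forward transform of both images; the
   `fusion_depth` finest scales are taken from the equalized reference, all
   coarser scales (which carry the band's mean and low-frequency chemistry)
   from the interpolated band (`split_by_scale()`).
3. **Inverse transform** returns the sharpened band.

`fusion_depth` defaults to `ceil(log2 s)` — the number of dyadic scales
whose frequency content is lost at decimation factor `s` — clamped to
`n_scales - 1` so the coarsest scale always comes from the interpolated
band; without the clamp the band's mean absorbance would be overwritten by
the reference's. "High-frequency components" are substituted at whole-scale
granularity, all orientations included: the near-horizontal frequency
wedges are not degraded by y-decimation, but selective orientation fusion
would add a tuning surface with little benefit on tested phantoms; it is
left as an extension.

### The curvelet transform (`fdct_forward()`, `fdct_inverse()`)

No R curvelet implementation exists, so the package provides a
frequency-wrapping fast discrete curvelet transform built for exact
invertibility:

* **Radial windows**: Meyer-style smooth transitions
  (`cos/sin(π/2·ν(t))` with the quartic auxiliary polynomial ν) between
  dyadic concentric-square boundaries at `ρ = 2^{-m}` of Nyquist. The
  squared low/high pair sums to 1 exactly at every frequency sample.
* **Angular windows**: within each annulus, wedges are the square roots of
  a telescoping partition built from ν-steps, centered so that (for angle
  counts divisible by 4) the axes are wedge centers. Squares again sum to
  1 exactly.
* **Wrapping**: each windowed wedge is cropped to the bounding box of its
  frequency support and inverse-transformed on that small grid with
  unitary FFTs. Cropping a contiguous support is injective, so synthesis —
  re-transform, re-window, accumulate, one inverse FFT — reconstructs the
  image exactly; no power-of-two padding is needed and non-square sizes
  work directly.

Because the squared windows tile frequency space exactly, the frame is
tight to machine precision: round-trip and Parseval errors measure ~1e-15
(asserted below 1e-6 in the tests, on 32×32, 64×64 and 100×60 images).
Orientation counts start at `n_angles_coarse` (default 16) at the second
scale and double every second scale; the finest scale is an isotropic
wavelet ring by default (CurveLab's convention, avoiding directional
artifacts at the highest frequencies). Coefficients are complex, and
wedges come in antipodal pairs: a real image's spectrum is Hermitian, so
one *spatial* orientation corresponds to a ±θ wedge pair. Tests of
orientation selectivity therefore group antipodal pairs: a horizontal edge
puts all of its finest-scale energy into the single pair containing the
vertical frequency axis.

## The synthetic phantom (`phantom_spec()`, `generate_phantom()`)

No public O-PTIR TMA data exist, so validation runs on synthetic
tissue-core phantoms with known ground truth:

* **Geometry**: 96×96 px at 0.5 µm pitch; class regions are quantile
  thresholds of Gaussian-smoothed white noise with an 8 µm correlation
  length — a few organically shaped blobs per core, so class boundaries
  (where spectra mix) occupy a small fraction of pixels, as in real cores
  at this magnification. Each class must hold ≥ 2% of pixels; degenerate
  draws are retried deterministically.
* **Spectra**: three classes (epithelium-, stroma-, necrosis-like). Each
  class spectrum is a shared tissue base (Gaussian peaks near amide I
  ~1660, amide II ~1545, carbohydrate ~1036 cm⁻¹, ...) scaled by a
  class-specific gain, plus 3–6 smaller class-specific peaks, with
  pairwise spectral angles ≥ 5°. The shared base is essential: real MIRSI
  band images are strongly spatially correlated because all bands ride on
  common protein content, and this correlation is the premise of affine
  equalization against a single reference band. Phantoms with fully
  independent class spectra break that premise and make reference fusion
  inject mis-scaled edges — a phantom artifact, not a property of the
  method.
* **Degradations**: isotropic Gaussian blur (σ = 1 px, optical) and
  additive i.i.d. Gaussian noise (sd 0.01 absorbance; the instrument's
  noise is not otherwise characterized). The generator is a pure function
  of its spec, seed included.

What the phantom does *not* model: scattering and baseline artifacts,
stage-motion distortion, physically accurate photothermal signal
formation, or pathologist-grade morphology. Passing phantom tests
demonstrates that the reconstruction preserves spatial detail and
class-discriminative chemistry under controlled conditions; it does not
certify the accuracies reported on real tissue.

## Quality metrics and the spacing sweep

`mse()` and `ssim()` follow the standard definitions (SSIM: 11×11 Gaussian
window, σ 1.5, k₁ = 0.01, k₂ = 0.03, valid-mode filtering). The SSIM
dynamic range is taken from the ground-truth band in
`evaluate_reconstruction()` — a candidate cannot inflate its score by
inflating its range — and from the pooled pair in bare `ssim()` calls,
which keeps the function symmetric. Metrics are computed per band and then
averaged (a joint whole-cube variant is available via `joint = TRUE`).

`spacing_sweep()` repeats phantom → decimate → interpolate → fuse → score
over replicate phantoms (the count is a parameter, default 4 — the same
order as the handful of replicate cores such metric experiments use in
practice) and y spacings, reporting means
and n−1 standard deviations. The monotone-degradation experiment holds
`fusion_depth` fixed at 2 across spacings: one reconstruction algorithm is
applied at every spacing, so the trend isolates sampling loss. (With the
adaptive default, spacing 1 µm substitutes fewer scales than spacing 2 µm
and its SSIM drops below the spacing-2 value — a parameter-coupling
artifact, not a sampling effect.)

At full sampling (`s = 1`, window off, no fusion) the sweep's MSE equals
the realized noise power `noise_sd²` — the analytic floor, asserted within
3 standard errors in the tests.

## Segmentation harness

`sample_training_pixels()` draws equal pixel counts per class to prevent
class bias (default 500 per class at phantom scale — the desk-scale analog
of the ~10,000 per class a full TMA supports) from the
27 non-reference bands. The classifier is a seeded random forest (100
trees, √p feature subsampling — conventional defaults, exposed as
arguments); any patch classifier exposing class-probability planes can be
evaluated through `evaluate_segmentation()`. Train/test mimics the
TMA-half protocol: right half trains, left half tests. Reported figures:
per-class recall, overall accuracy (the support-weighted mean of class
recalls, which is algebraically identical to the raw pixel-match
fraction — both fields are reported), a confusion matrix, and one-vs-rest
AUCs by trapezoidal ROC integration (cross-checked against pROC in the
tests; ties grouped by threshold; classes absent from the truth yield NA,
not 0). Probability argmax ties break toward the lower class index.

On default phantoms reconstructed at `s = 10`, held-out overall accuracy
runs in the low-to-mid 90s (percent). Accuracies above 95% reported for
real tissue with CNN classifiers and millions of training pixels are a
different regime and are not claimed here.

## Numerical and I/O choices

* Images are `[row, col]`, 0-based in all conventions, origin top-left;
  sparse row *i* ↔ dense row *i·s* (row 0 retained), and
  `rows_lo = ceil(rows_hi/s)` keeps the final partial stride.
* The default band set is 27 fingerprint-region wavenumbers between 908
  and 1786 cm⁻¹ plus the 1660 cm⁻¹ Amide I reference — 28 bands in total.
* ENVI storage is BSQ, 32-bit little-endian float — the exact round-trip
  format. TIFF export quantizes each band to 32-bit integers with
  scale/offset in a JSON sidecar (baseline TIFF writers in R do not store
  float samples); quantization error is ~2×10⁻¹⁰ of the band range, below
  single precision.
* Validation never raises: `validate_cube()` returns human-readable
  violations, flagging |A| > 5 as suspicious rather than illegal (noise
  may dip absorbance slightly negative).
* The pipeline derives per-stage seeds from the global seed by hashing
  stage names, so any stage can be rerun in isolation; manifests record
  MD5 checksums, and identical configurations reproduce identical bytes.

## Problem sizes

Tests and the acceptance script run on 96×96 phantoms with 28 bands (the
sweep: 4 replicates × 5 spacings), 48×48 8-band phantoms for unit tests,
and 32–128 px images for transform properties. These sizes were chosen so
the full suite exercises every code path at desk scale; the algorithms are
O(B·N log N) in pixels and bands and run unchanged on full-size cores.

## Known limitations

* Only integer y-decimation factors and 1-D (y-axis) sparsity are
  supported; 2-D sparse patterns and compressed-sensing reconstruction are
  out of scope.
* Fusion benefit depends on inter-band structural correlation; bands that
  are structurally unlike the reference (rare in tissue, possible in
  mixed-material samples) can be degraded by injected reference detail —
  at low noise and rich edges the benefit is systematic, at high
  smoothness or high noise it can vanish band by band.
* The SSIM benefit of fusion is asserted at phantom scale (96 px); at very
  small image sizes (≤ 48 px) boundary wedges dominate and structural
  scores are unreliable.
* The curvelet implementation favors exactness and clarity over speed; it
  is not optimized for very large single images (wedge windows are dense
  matrices).
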