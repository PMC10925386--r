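# sparseptir

Reconstruction of high-resolution optical photothermal infrared (O-PTIR)
hyperspectral images from sparse, y-interleaved acquisitions — plus the
evaluation apparatus (MSE/SSIM spacing sweeps, pixel-wise tissue-subtype
classification) needed to qualify the reconstruction on synthetic tissue
phantoms with known ground truth.

## Who this is for

O-PTIR microscopes measure mid-IR absorbance at 0.5 µm resolution but
raster-scan slowly: imaging time grows with the number of scanned rows
times the number of spectral bands, making a 28-band stack of a tissue
core take tens of hours. If you are building or evaluating sparse-scan
protocols for discrete-frequency IR imaging — or need a reference
implementation of reference-band curvelet fusion with a numerically exact
discrete curvelet transform in R — this package is for you.

## The method

Acquire one band (Amide I, 1660 cm⁻¹) at full resolution and every other
band with only every *s*-th row (pixel pitch `dy_lo = s · dy_hi`; at the
recommended 0.5 µm × 5 µm spacing, `s = 10` and only 10% of each sparse
band is measured). Reconstruction is two-stage, per band *b*:

1. **Fourier zero-pad interpolation** — FFT each column along y, center,
   zero-pad to the reference grid, apply a Gaussian frequency window
   (half-gain at the low-resolution Nyquist), inverse FFT, rescale by
   `rows_hi / rows_lo` so the band mean is preserved.
2. **Curvelet fusion** — least-squares affine equalization
   `argmin_{a,b} Σ (a·ref + b − band)²` brings the reference onto the
   band's intensity scale; the `ceil(log₂ s)` finest scales of the band's
   curvelet pyramid are then replaced by those of the equalized reference
   and the transform inverted, restoring the edges lost to decimation
   while the coarse scales keep the band's chemistry.

The bundled curvelet transform is a wrapping-type FDCT built from
Meyer-style polar wedge windows whose squares tile the frequency plane
exactly — a tight frame with round-trip and Parseval errors at machine
precision (~1e-15), on non-square and non-power-of-two images.

Because no public O-PTIR tissue data exist, the package ships a synthetic
tissue-core phantom generator (class blobs, per-class absorbance spectra
with a shared tissue base, blur, noise) and harnesses that score
reconstructions by MSE/SSIM against ground truth and by whether a
random-forest pixel classifier trained on reconstructed spectra still
separates tissue classes.

## Worked example

```r
library(sparseptir)

spec   <- phantom_spec(boundary_smoothness = 3, noise_sd = 0.005)  # edge-rich core
ph     <- generate_phantom(spec)
scheme <- sampling_scheme(dy_lo = 5)          # 0.5 x 5 um -> s = 10
sampling_fraction(scheme)
#> [1] 10

sparse <- subsample_y(ph$noisy_cube, scheme)
sparse
#> <sparse_cube> reference 96 x 96 px at 1660 cm^-1; 27 sparse bands 10 x 96 px (s = 10)

interp <- interpolate_cube(sparse)
recon  <- reconstruct_cube(sparse)

ei <- evaluate_reconstruction(ph$clean_cube, interp, "interpolated")
ef <- evaluate_reconstruction(ph$clean_cube, recon,  "fused")
cat(sprintf("interpolated: MSE %.5f SSIM %.3f\nfused:        MSE %.5f SSIM %.3f\n",
            ei$mean_mse, ei$mean_ssim, ef$mean_mse, ef$mean_ssim))
#> interpolated: MSE 0.00218 SSIM 0.408
#> fused:        MSE 0.00191 SSIM 0.517
```

Only 10% of each non-reference band was measured, yet curvelet fusion cuts
the mean per-band reconstruction error by ~12% relative to plain Fourier
interpolation and raises mean SSIM from 0.41 to 0.52 — the injected
reference detail restores the edges interpolation cannot.

The full chain (phantom → subsample → interpolate → reconstruct →
evaluate → segment, with a checksum manifest) runs via

```r
run_pipeline(run_config(outdir = "run1", seed = 42))
```

or from a shell through the thin CLI:

```sh
Rscript inst/cli/sparseptir.R run-all --outdir run1 --seed 42
```

## Layout

* `R/` — data model (`hyper_cube`, `sparse_cube`), ENVI/TIFF/CSV I/O,
  phantom generator, Fourier interpolation, curvelet transform, fusion,
  quality metrics, segmentation harness, pipeline.
* `tests/testthat/` — unit, property and acceptance suites (all fixtures
  generated in code).
* `vignettes/sparse-reconstruction.Rmd` — the model, parameter rationale,
  phantom design, numerical choices, and limitations.
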