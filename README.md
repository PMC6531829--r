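# hyperdim

Analysis toolkit for **hyperdimensional imaging microscopy (HDIM)** — laser
scanning microscopy in which every pixel records photon counts simultaneously
across emission wavelength, polarization state and photon arrival time. Under
the default detection geometry (16 spectral bins × 2 polarizations × 64 TCSPC
time bins) each pixel carries a 2048-value *hyperdimensional spectral
signature* (HDSS). The package is aimed at microscopists and image analysts
who want to work with such data — or to prototype against realistic synthetic
data — without instrument-vendor software.

## What it does

* **Container** — `hdim_stack()`: a calibrated 5-D photon-count histogram
  `(row, col, spectral, polarization, time)` with a versioned HDF5 on-disk
  format (`write_hdim()` / `read_hdim()`), multi-page TIFF import/export with
  JSON sidecars, and conservation-safe projections: `project()` sums counts
  over any axis subset and always preserves the photon total exactly;
  `spatial_bin()` sums *k*×*k* pixel blocks.
* **Per-pixel spectroscopy** — the classical projections of the HDSS:
  * spectral peak: argmax over wavelength bins, refined by three-point
    parabolic interpolation δ = ½(c₋₁ − c₊₁)/(c₋₁ − 2c₀ + c₊₁);
  * mean fluorescence lifetime: the barycenter (mean arrival time)
    τ̄ = Σ(tᵢ − t₀)cᵢ / Σcᵢ of the magic-angle total-intensity decay
    I∥ + 2G·I⊥, with an optional closed-form truncation correction
    (a mono-exponential decay observed over a window T has mean arrival time
    τ − T/(e^{T/τ} − 1));
  * steady-state anisotropy: r = (I∥ − G·I⊥)/(I∥ + 2G·I⊥).
* **PCA contrast enhancement** — `pca_train()` pools the pixels of a set of
  stacks (4×4 spatially binned, count-normalized by default) and fits
  covariance PCA over the flattened HDSS vectors; `pca_apply()` produces
  per-pixel score maps at full resolution.
* **Digital staining** — `render_he_like()` / `render_dab_like()`: the first
  three (four) PCA components are robustly stretched,
  PCA′ = (PCA − min)/(s·(median + 3SD − min)), assigned to the magenta, cyan,
  black (and yellow) channels of a CMYK composite and projected to RGB —
  renderings that mimic hematoxylin–eosin and DAB histopathology
  counterstains. `true_color()` renders the spectral projection through a
  CIE-1931-based eye-sensitivity matrix.
* **Separability statistic** — for labeled pixel clusters *i*, *j* with
  centroids μ and per-dimension variances σ²,

  S<sub>ij</sub> = ‖μᵢ − μⱼ‖₂ / √Σ_d (σ²ᵢ,d + σ²ⱼ,d).

  `dimensionality_sweep()` tabulates the worst-resolved pair and mean S over
  feature spaces of growing dimensionality ({peak} → {peak, τ̄} →
  {peak, τ̄, r} → PCA planes).
* **Photophysics simulator** — `simulate_panel()` regenerates a 12-solution
  reference experiment entirely in silico: FITC-like and R6G-like emitters
  (Gaussian spectra), Stern–Volmer collisional quenching
  τ = τ₀/(1 + K·[Q]), Perrin depolarization r = r₀/(1 + τ/θ) with
  viscosity-scaled rotational correlation times, two-photon photoselection
  (r₀ ceiling 4/7 ≈ 0.57 vs 2/5 for one-photon), exact per-bin integration of
  the polarized decays, and Poisson photon counting. Compositions
  {F, R, D(mixture)} × environments {0, G(lycerol), Q(uencher), B(oth)} give
  the 12 labeled conditions F0 … DB.

## Worked example

Simulate the 12-condition panel at 32 × 32 px, train PCA, and sweep the
separability of the 12 pixel clusters across feature spaces:

```r
library(hyperdim)
res <- reproduce_panel(geometry = hdim_geometry(32, 32), seed = 1)
res$stacks$F0
#> <hdim_stack> 32 x 32 pixels, 16 spectral x 2 polarization x 64 time bins (2048 values/pixel)
#>   wavelength: 426.2-613.8 nm | time window: 12.50 ns | excitation: 840 nm | G = 1
#>   total photons: 10,240,555
res$sweep
#>                      space dimensionality worst_pair_i worst_pair_j  worst_S mean_S
#> 1                     peak              1           F0           FG 0.000597   8.79
#> 2            peak+lifetime              2           R0           RG 0.006898  15.87
#> 3 peak+lifetime+anisotropy              3           R0           D0 2.293484  18.26
#> 4                     pca2              2           R0           RQ 6.667973  29.29
#> 5                     pca3              3           R0           RQ 9.658180  25.80
```

Read: on spectral peak alone the quenched/viscous variants of the same dye
are unresolvable (worst-pair S ≈ 0 — quenching does not move the emission
spectrum); adding lifetime and anisotropy resolves every pair
(worst S ≈ 2.3), and the first two PCA components resolve the closest pair
about three times better still — the contrast-enhancement claim in
quantitative form. The per-pixel estimators track the generating physics:

```r
median(map_values(anisotropy_map(res$stacks$F0)))  # 0.029 (fast rotor)
median(map_values(anisotropy_map(res$stacks$FG)))  # 0.255 (glycerol-slowed)
```

Digital stains from the score maps:

```r
maps <- pca_apply(res$model, res$stacks$D0)
img <- render_he_like(maps, stain_params(s = "auto"))
write_rgb_png(img, "D0_he.png")
```

A command-line front end wraps the same pipeline
(`Rscript inst/cli/hdim.R simulate --seed 1 --out runs/panel`, then
`features`, `pca`, `stain`, `separability`, `reproduce-panel`); every run
writes a `manifest.json` sufficient to re-run it bit-identically.

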