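---
title: "Models and methods behind hyperdim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hyperdim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperdim)
```

# The data model

Hyperdimensional imaging microscopy records, for every image pixel, a photon
histogram over emission wavelength, polarization state and photon arrival
time. `hyperdim` fixes one canonical array layout,
`(row, col, spectral, polarization, time)`, enforced at construction and on
every read — a single fixed axis order is the cheapest defence against silent
transposition bugs. The default detection geometry is 16 spectral bins × 2
polarizations × 64 time bins, i.e. a 2048-value signature per pixel.

Axis defaults are explicit, overridable assumptions rather than measured
calibrations:

* **Time axis**: 64 uniform bins over one laser repetition period, default
  12.5 ns (an 80 MHz Ti:sapphire oscillator). Time-domain calibration against
  an instrument response function is out of scope; the delta-IRF assumption
  is discussed below.
* **Wavelength axis**: 16 uniform bins over a 200 nm band starting at
  420 nm, matching a compact grating spectrograph. Spectral calibration
  against laser lines is an instrument procedure, not a data-analysis one.
* **G-factor**: the detection-balance correction between the two
  polarization channels defaults to 1 and is applied only where polarization
  channels are combined (anisotropy, magic-angle lifetime). It is carried in
  the container so a measured value survives round trips.

Projections (`project()`) are pure sums over axis subsets: photon totals are
conserved exactly in integer arithmetic and collapses commute, which the test
suite checks property-style over randomized stacks. Spatial binning drops
ragged edge blocks instead of padding them — no photons are invented, and the
retained area conserves its counts exactly.

The on-disk container is a single HDF5 file (integer `/counts`, `/axes/*`,
`/meta/*`, a format-version dataset and a JSON provenance string). Missing
datasets and version mismatches are rejected by name. A plain multi-page
TIFF import/export with a JSON axis sidecar is provided for interoperability;
feature maps export as 32-bit TIFF min–max scaled to [0, 1] with the exact
scale recorded in a JSON sidecar (the bundled TIFF writer has no native
float-sample mode, and the sidecar makes the export losslessly invertible).

# The forward model (simulator)

The simulator exists so that every downstream stage — estimators, PCA,
stains, separability — can be validated against known ground truth. Its
defaults regenerate a 12-solution reference panel: compositions
F (FITC-like, 10 µM), R (R6G-like, 1 µM) and D (their mixture), each in four
environments — `0` buffer, `G` glycerol (rotation slowed), `Q` collisional
quencher (lifetime shortened), `B` both.

Per fluorophore and environment the model factorizes as
*spectral fractions ⊗ polarized decay fractions*, scaled by
brightness × concentration, summed over fluorophores, and sampled as
independent Poisson counts:

* **Spectra** are Gaussians integrated exactly over the wavelength bins and
  renormalized in-band.
* **Lifetime** follows Stern–Volmer quenching, τ = τ₀/(1 + K·[Q]).
* **Rotation** follows the Perrin picture: a single rotational correlation
  time θ = θ₀ × viscosity factor, giving
  r(t) = r₀·e^{−t/θ} and the steady state r = r₀/(1 + τ/θ).
* **Photoselection** sets the anisotropy ceiling
  r₀ = (2n/(2n+3))·(3cos²β − 1)/2: 2/5 for one-photon and 4/7 ≈ 0.57 for
  two-photon excitation with collinear dipoles. The default panel uses the
  two-photon ceiling.
* **Polarized decays** I∥(t) ∝ e^{−t/τ}(1 + 2r(t)),
  I⊥(t) ∝ e^{−t/τ}(1 − r(t)) are integrated in closed form over each time
  bin, so every simulated expectation has an analytic oracle.

## Parameter choices

The reference experiment prints concentrations but no photophysical
constants, so the defaults are literature-typical synthetic stand-ins,
chosen once and documented here:

| parameter | FITC-like | R6G-like | rationale |
|---|---|---|---|
| emission peak | 517 nm | 552 nm | typical aqueous emission maxima |
| Gaussian σ | 30 nm | 20 nm | fluorescein is the broader emitter |
| τ₀ | 4.0 ns | 4.1 ns | typical unquenched lifetimes |
| K (per mM) | 8 | 5 | free parameters; at [Q] = 0.1 mM they shorten τ to ~2.2 / 2.7 ns, the clearly-resolved quenching contrast the reference panel exhibits |
| θ₀ | 0.2 ns | 0.3 ns | small-dye rotational times in water |
| viscosity factor (G/B) | 15 | 15 | ≈ bulk viscosity ratio of 65 % v/v glycerol : water |
| brightness (photons/µM/px) | 1000 | 10000 | equal yields (10⁴ photons/pixel) at the panel concentrations, mirroring the matched-brightness design |

Brightness equalization matters: it makes the D mixtures genuinely ambiguous
between their components, which is what makes the unmixing problem
non-trivial.

## Truncation, wrap-around and the IRF

Two modeling switches deserve explanation.

**IRF.** The default instrument response is a delta function at the first
bin edge. This keeps every oracle closed-form. Real TCSPC systems convolve a
finite IRF (tens to hundreds of ps); for barycenter lifetimes this shifts
t₀, which is why `mean_lifetime_map()` exposes `t0` as a parameter.

**Decay truncation vs wrap-around.** By default expected decays are computed
on the window [0, T] with no contribution from preceding pulses. A
mono-exponential decay so truncated has mean arrival time
τ − T/(e^{T/τ} − 1), which is the oracle the lifetime tests use, and
`truncation_correction = TRUE` inverts that relation numerically. The
opt-in `wrap_around = TRUE` folds the incomplete decays of all preceding
pulses into the window (the periodic steady state of a high-repetition-rate
laser), dividing each exponential term by 1 − e^{−T/τc}. The choice
interacts with anisotropy: under truncation, late (depolarized) photons are
preferentially lost, so the window-integrated anisotropy sits *above* the
Perrin value — by ~0.01 for θ in the nanosecond range at T = 12.5 ns, τ = 4
ns. Under wrap-around the integrated channel ratio reproduces the Perrin
steady state exactly. Accordingly, the anisotropy-recovery tests run on
wrapped expectations (where the Perrin value is the exact truth) and a
separate test bounds the truncation bias; lifetime recovery uses the
truncated closed form. Neither switch changes the estimators — only the
simulated physics.

# Per-pixel estimators

**Spectral peak.** The literal reading of "peak" — argmax over wavelength
bins — refined by three-point parabolic interpolation,
δ = ½(c₋₁ − c₊₁)/(c₋₁ − 2c₀ + c₊₁) bin widths, which is exact for a locally
quadratic spectrum and degrades gracefully to the bin center on degenerate
triplets; edge maxima are returned unrefined. An intensity-weighted centroid
is available (`method = "centroid"`) for users who prefer a dispersion-style
statistic.

**Mean lifetime.** The barycenter (mean arrival time) of the total-intensity
decay. The decay is formed with the magic-angle weighting I∥ + 2G·I⊥: for a
rotating emitter the plain channel sum I∥ + I⊥ retains a fast
anisotropy-decay component (rate 1/τ + 1/θ) that biases the barycenter early
by up to ~2 % at the default parameters, whereas the magic-angle combination
is exactly ∝ e^{−t/τ}. The plain sum is available as
`polarization_weight = "sum"`. The estimator deliberately avoids decay
fitting: it is closed-form testable, monotone in τ, and adequate for
contrast; multi-exponential fitting and phasor analysis are out of scope.

**Anisotropy.** r = (I∥ − G·I⊥)/(I∥ + 2G·I⊥) after collapsing spectral and
time axes. Zero denominators are masked, never thrown. The default masking
threshold for all feature maps is 100 photons/pixel: anisotropy noise scales
as 1/√N, and below ~100 photons the maps are dominated by shot noise.

# PCA contrast enhancement

`pca_train()` pools pixels of all input stacks (after 4×4 spatial binning,
which cuts the ensemble 16-fold while quadrupling per-vector SNR) and fits
covariance PCA about the global ensemble mean. Design choices:

* **Normalization.** Training happens on binned pixels (~16× the photons of
  raw pixels) but application happens at full resolution. With raw count
  vectors the transform would not transfer across that count scale, so the
  default normalizes each pixel vector to unit total count; `raw` mode
  mimics the literal unnormalized reading. The gap is flagged in the
  function documentation.
* **Covariance, not correlation** — all HDSS entries share units.
* **Global centering** across the pooled ensemble (per-stack centering would
  remove exactly the between-condition contrast the method is after).
* **Deterministic signs**: each loading's largest-magnitude entry is made
  positive; PCA signs are otherwise arbitrary and would flip between runs.
* Implementation is SVD-based (`stats::prcomp`); the test suite checks it
  against an independent brute-force eigendecomposition of the sample
  covariance matrix.

# Digital stains

Score maps are stretched to [0, 1] as
PCA′ = (PCA − min)/(s·(max\* − min)) with min the image minimum and
max\* = median + 3·SD computed over unmasked pixels — a robust ceiling that
moderates noise-driven outliers. `s` is either fixed (default 1, at which
the anchors are exact: min → 0, max\* → 1) or `"auto"`. The auto rule as
inherited was ambiguous (it asks simultaneously for s ≥ 1 and for the 95th
percentile to land at 1, which conflict when the percentile falls below
max\*); `hyperdim` resolves it as s = max(1, (q₉₅ − min)/(max\* − min)): s
rises above 1 only when more than 5 % of pixels would clip, honouring both
the saturation intent and the s ≥ 1 constraint.

The HE-like stain maps stretched PC1 → magenta, PC2 → cyan, PC3 → black,
yellow empty; the DAB-like stain adds PC4 → yellow. CMYK → RGB uses the
naive device-independent conversion R = (1−C)(1−K) etc. — reproducibility is
preferred over ICC colorimetric fidelity, and no specific commercial stain
palette is targeted. A constant score map (stretch undefined) renders as
zeros with a warning rather than failing.

`true_color()` uses CIE 1931 2° color-matching functions — the multi-lobe
Gaussian analytic approximation, accurate to ~1 % of the tabulated curves —
sampled at the spectral bin centers, composed with the linear sRGB primary
matrix, negative weights clipped. The matrix is a plain argument, so any
other eye-sensitivity model drops in.

# Separability

For clusters *i*, *j*: S = ‖μᵢ − μⱼ‖₂ / √Σ_d(σ²ᵢ,d + σ²ⱼ,d), with unbiased
per-dimension sample variances summed over the dimensions of both clusters
("root sum" implemented literally; averaging instead of summing would scale
S by √2 uniformly and change no ordering). Physical feature spaces mix nm,
ns and dimensionless units, so by default each dimension is standardized by
the pooled within-cluster SD before computing S — this makes S invariant
under per-dimension rescaling, at the price of making it a relative
statistic. PCA-score spaces are left raw: scores share units and raw S is
invariant under the orthogonal rotation PCA applies. Pairs with S < 1
(centroid separation below the pooled spread) are labeled unresolved in
`tidy()`; the threshold is presentation-only.

`dimensionality_sweep()` reruns the matrix over an ordered list of feature
spaces. On the default simulated panel the sweep reproduces the method's
central claim: the worst-resolved pair improves monotonically from {peak}
through {peak, τ̄} to {peak, τ̄, r}, and the first-two-PC plane resolves the
worst pair better than any physical 2-D space. The intuition is visible in
the degeneracies: quenching leaves spectra untouched (F0 vs FQ collapse in
peak space), glycerol leaves spectra and lifetimes untouched (F0 vs FG
collapse in {peak, τ̄}), while the 2048-value signature separates everything
the model can separate.

# Problem sizes and test design

The test suite validates estimator recovery at three scales, all chosen as
the package's own validation design: noise-free expected histograms (exact
oracles: truncated-exponential mean within half a time bin, Perrin/mixture
anisotropy within 10⁻³, spectral peak within half a bin), Poisson panels at
32 × 32 px and ~10⁴ photons/pixel (medians within 2 %, 0.01 and half a bin),
and one full end-to-end panel at 64 × 64 px with a pinned seed for the
separability sweep. Conservation properties run over 100 randomized small
stacks. The Poisson-realism check verifies mean–variance agreement within
5 % over 10⁴ replicate pixels.

What passing these tests shows — and what it does not: the synthetic panel
has Gaussian spectra, mono-exponential decays, a single rotational
correlation time, a delta IRF, no detector afterpulsing, pile-up,
background, or photobleaching, and spatially uniform scenes. Real specimens
violate most of these. The tests therefore certify the *analysis chain*
(estimators, PCA transfer, stain determinism, separability accounting), not
instrument realism. Excited-state reactions, FRET, NMF/ICA unmixing,
time-resolved anisotropy fitting and SDT vendor-file parsing are explicit
non-goals.

# Degenerate inputs and numerical conventions

* Zero-count pixels: masked (`NA`) in every feature map; never an error.
* Zero denominators in anisotropy: masked per pixel.
* Constant score maps: all-zero stretch plus warning.
* Uniform histograms under truncation correction: mapped to `Inf`
  (the τ → ∞ limit of a window-uniform decay).
* Parabolic refinement with a degenerate (flat) triplet: δ = 0.
* Singleton clusters: variance contribution 0, flagged with a warning;
  zero pooled variance with distinct means reports `Inf`, flagged.
* All randomness is seeded; per-condition seeds derive deterministically
  from the panel seed, and the RNG state of the caller is restored after
  simulation.
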