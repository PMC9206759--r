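---
title: "Covariance-matrix statistical adaptive weighting for MV ultrasound beamforming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariance-matrix statistical adaptive weighting for MV ultrasound beamforming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In synthetic transmit aperture (STA) ultrasound imaging each of the N array
elements transmits alone while all N receive, so two-way focusing can be
synthesized in software for every pixel.  The delay-and-sum (DAS) beamformer
is robust but blurry; the minimum-variance (MV, Capon) beamformer sharpens
the lateral point response dramatically but is notoriously poor at rejecting
incoherent noise and preserving the speckle texture clinicians read.  This
package implements a family of *pixel weights* that multiply the complex MV
output to suppress clutter and noise while retaining speckle:

* the coherence factor (CF) and generalized coherence factor (GCF) baselines,
* the covariance-matrix statistical factor (CMSF), and
* its coherence-adaptive refinement (CMSAW), the core method here,

together with DAS, MV, and eigenspace-based MV (ESBMV) reference
beamformers, a Field-II-style point-scatterer simulator, and the standard
image-quality metrics (lateral −6 dB FWHM, contrast ratio CR, generalized
contrast-to-noise ratio gCNR, speckle SNR sSNR).

## Data model and beamformers

After two-way delay compensation, pixel p carries an N×N matrix X(p) of
focused samples (transmit × receive).  The receive aperture is synthesized
by direct summation, x_i(p) = Σ_j w_j X(p)[i,j], giving the length-N
*aperture vector* x(p); DAS is the further transmit-weighted sum
Y_DAS = Σ_i w_i x_i.  All adaptive processing happens on the analytic
(Hilbert-transformed) signal so that conjugate-transpose operations and
envelope detection are well defined; the RF is never base-banded.

MV estimates a spatially and temporally smoothed covariance

    R(p) = Σ_{k=-K}^{K} Σ_{l=1}^{N-L+1} x_l(p+k) x_l(p+k)^H / ((2K+1)(N-L+1)),

loads it diagonally, R̂ = R + Δ·trace(R)·I, and solves for the
distortionless weights w = R̂⁻¹a / (a^H R̂⁻¹ a) with a = 1 (delays already
compensated); the output averages w^H x_l over the subarrays of the center
vector.  ESBMV projects w onto the eigen-subspace with eigenvalues
≥ γ·λ_max.

## The CMSF/CMSAW weighting chain

Per pixel, with σ the amplitude standard deviation (ASD) of the aperture
vector:

1. **Image-wide ASD normalization.**  σ' = σ^{−1/3} normalized by its image
   maximum, so σ' ∈ (0,1] and dim (noise-dominated) pixels map near 1.
2. **Dynamic subarray length.**  L' = ⌊σ'·L_max⌋, clamped below at 2.
3. **Spatial-only smoothing.**  R = (1/(N−L'+1)) Σ_l x_l x_l^H over the
   sliding L'-subarrays of the single center vector.
4. **Rotary averaging.**  R̂ = (R + J Rᵀ + J R J + Rᵀ J)/4 with J the
   exchange matrix — implemented exactly in this four-term form (a classic
   forward–backward mode `rotary = "classic_fb"` is provided for
   comparison).
5. **Diagonal reducing.**  Subtract δ times the diagonal part.  CMSF uses a
   constant δ; CMSAW uses the coherence-adaptive
   δ_ac = W_CF^{σ'} · δ_max ∈ [0, δ_max].
6. **Matrix MSR.**  The weight is the mean of all L'² entries divided by
   their population standard deviation, taken on real parts (the diagonal is
   real and the symmetrized off-diagonals are near-real; for real data this
   reduces exactly to the plain formulas).
7. **Application.**  Y = W × Y_MV on the complex image, before envelope
   detection; weight maps are not renormalized.

Why it works: coherent mainlobe pixels have large σ (amplitude-scaled
deviations), hence small L' — the reduced 2×2-ish matrix with its diagonal
removed has MSR ≈ 1.  Incoherent noise gets a large L' and a small δ_ac,
whose near-intact diagonal dominates a large matrix population and drives
the MSR far down.  In speckle, brighter pixels carry higher CF and thus a
larger δ_ac, which lowers their MSR relative to dimmer neighbours — an
anti-correlation with the envelope that compresses the speckle spread and
raises sSNR, which is precisely what the adaptive δ adds over constant-δ
CMSF.

## Parameters and defaults

| parameter | meaning | default | why |
|---|---|---|---|
| L | MV subarray length | N/2 | standard resolution/robustness compromise |
| Δ | diagonal-loading scale (ε = Δ·trace R) | 0.1/L | keeps R̂ well conditioned |
| 2K+1 | temporal (axial) smoothing window | 9 | study setting |
| γ | ESBMV eigen threshold | 0.5 | simulation-study setting |
| M0 | GCF low-frequency cutoff | 1 | speckle preservation + noise reduction |
| δ, δ_max | diagonal-reducing factors | 1 | simulation-study setting |
| L_max | maximum dynamic subarray length | N/2 | matches the MV subarray; the originating study leaves it unstated |
| ASD exponent | reciprocal compression | 1/3 | printed form; prose elsewhere suggests 1/2, the equation wins and the exponent is configurable |

Degenerate inputs are handled explicitly: zero-trace covariances skip
loading with a warning; singular solves fall back to uniform weights and are
counted in the run log; L' ≤ 2 clamps to 2; an exactly-zero reduced matrix
gets weight 0 while a nonzero all-equal matrix returns the configurable cap
(1e6); σ is floored at 1e-12×max(σ) before the reciprocal; σ' is floored at
1e-6 inside the power law so 0⁰ never evaluates.  When every eigenvalue
passes the ESBMV threshold the projector is the identity and the MV weights
are reused exactly, so γ→0 reproduces MV bit for bit.

## The synthetic-data generator

`sta_presets()$simulation` encodes the reference study conditions: a
64-element, 0.24 mm pitch, 3.33 MHz linear array sampled at 40 MHz in a
1540 m/s medium; a 22 × 0.5 × 15 mm phantom of uniformly placed scatterers
with zero-mean Gaussian amplitudes at 40 per resolution cell; a 5 mm
diameter anechoic cyst; three strong point targets; and 10 dB additive
Gaussian channel noise (variance set from the mean power of the nonzero
signal support).  The resolution cell is (λ·z_mid/D) × elevation extent ×
c/(2B) with B the −6 dB pulse bandwidth.  Echoes are Gaussian-enveloped
cosines (60 % fractional bandwidth — the original excitation is not
specified, so this is our choice and it is exposed in `pulse_model()`) at
the exact two-way delays with optional 1/(d_tx·d_rx) spreading; transmit/
receive reciprocity halves the work.  All randomness flows through one
explicitly seeded generator and never touches the caller's RNG state.

Unstated layout details were fixed once: point targets at x = −7 mm and
depths 20/24/28 mm, cyst centered at (5.5, 24) mm, point scatterer
amplitude 80 (putting point peaks roughly 25–30 dB above the speckle floor
while keeping their sinc-type sidelobes below the speckle level inside the
background ROI, which sits ≥5 mm away at matched depth), cyst ROI eroded by
about one beamwidth (radius 1.7 mm), background ROI x ∈ [−2, 2] mm,
z ∈ [21.75, 26.25] mm.  `sta_presets()$toy` is an N = 32, 10-scatterers-
per-cell reduction of the same design used by the fast tests.

What the generator does **not** emulate: element directivity and baffle
obliquity, transducer impulse responses, attenuation, nonlinearity, and
elevation focusing.  Consequently the simulated system point-spread
function is *sharper* than a physically measured one — our DAS −6 dB width
at the 24 mm point is ≈0.66 mm against the ideal sinc² value of 0.60 mm,
whereas full transducer-physics simulations of the same geometry report
≈0.86 mm — and the MV-family FWHMs scale down with it.  Passing tests
therefore demonstrate the statistical and ordering behaviour of the
weighting chain, not absolute resolution figures of real transducers.

## Numerical and measurement choices

* **Imaging grid.**  Lateral spacing ≤ pitch/4 near point targets (0.02 mm
  in the studies) to keep FWHM discretization error small; axial spacing
  0.1 mm so that the 9-point temporal window spans ≈0.8 mm — about one
  pulse length, the scale over which axial speckle decorrelates.  A much
  finer axial grid would make the nine covariance samples nearly identical
  and waste the temporal average (visible as degraded MV speckle SNR).
* **Study problem sizes.**  The full-scale runs beamform ~12–50 k pixels
  over a band covering the 24 mm point, the cyst, and the background ROI;
  the σ' normalization pass runs over whatever grid is supplied, so grids
  should include the dimmest region of interest (the cyst interior) for
  weights comparable to full-frame processing.
* **Linear solves**, never explicit inverses, for the MV weights; failures
  after loading fall back to uniform weights and are logged per pixel.
* **FWHM** interpolates linearly in dB between lateral samples through the
  peak's axial row; **gCNR** uses 256 equal-width bins over the pooled
  envelope range (configurable; ~10³ pixels per ROI keep the histogram
  overlap estimate stable); **CR** and **sSNR** use pre-compression
  envelope means/population standard deviations.  All four are invariant
  to a global positive rescaling of the envelope.
* **Speckle-statistics checks** run on homogeneous blocks with a narrow
  depth span, because geometric spreading imposes a deterministic axial
  gain gradient that inflates the envelope standard deviation.  At toy
  scale a single realization holds only tens of independent speckle cells,
  so Rayleigh-band assertions are made on multi-seed ensembles.

## Known limitations

* Hyperechoic targets: the dynamic subarray length shrinks over strong
  off-axis scattering, so CMSF/CMSAW weights can depress bright lesions —
  a known trade-off of the method family, not corrected here.
* The MSR weight is a ratio of small-sample statistics; below N ≈ 64 its
  pixel-to-pixel variance erodes the speckle-SNR advantage of CMSAW over
  constant-δ CMSF (the toy aperture shows it only weakly; the full
  64-element runs show it clearly).
* No HDF5/MAT container bindings are shipped; channel data enter as plain
  R arrays through `channel_data_cube()`, and configurations/metrics round-
  trip through YAML/CSV/JSON.

## A worked example

```{r, eval = FALSE}
library(cmsaw)
p <- sta_presets()$toy
ph <- p$phantom; ph$rng_seed <- 11L
field <- make_scatterers(ph, p$geometry, p$pulse)
cube <- add_channel_noise(simulate_sta(field, p$geometry, p$pulse),
                          p$snr_db, 12L)
grid <- imaging_grid(seq(-6e-3, 5.2e-3, by = 0.06e-3),
                     seq(18e-3, 22e-3, by = 0.1e-3))
imgset <- beamform_image(cube, grid, p$config)
image_metrics(imgset, p$rois)
plot(imgset, "CMSAW-MV", dynamic_range_db = 60)
```
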