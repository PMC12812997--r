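---
title: "Measuring low-level visual psychophysics in image-computable models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring low-level visual psychophysics in image-computable models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Claims that deep networks "model the visual brain" are usually backed by
object-recognition benchmarks, which say little about the adaptive
bottleneck of the retina--V1 pathway: spectral sensitivity, brightness and
chromatic adaptation, contrast sensitivity, and the rich masking phenomena
that define low-level human vision. `decalogue` packages a battery-based
alternative: it synthesizes calibrated stimulus series for ten classical
psychophysical properties, drives any image-computable model through them
with a simple, explicit read-out, and scores the resulting response curves
against packaged human references.

The pipeline has four parts, mirroring how a psychophysicist would run the
experiment:

1. **Stimuli** -- calibrated test/background image pairs per property.
2. **Read-out** -- a rule converting model activations to a scalar
   "visibility" per pair.
3. **Ground truth** -- standard human sensitivity curves and known curve
   orderings.
4. **Scoring** -- grouped Pearson correlation, Kendall rank correlation of
   curve orderings, plain-average aggregation with a bootstrap interval,
   and two-sample Kolmogorov--Smirnov comparison between models.

## Calibration model

All stimuli live in a calibrated opponent space: an achromatic plane `A`
(CIE luminance, cd/m²) and two chromatic planes `T` (red--green) and `D`
(yellow--blue) in linear tristimulus units. The opponent axes are a
Jameson--Hurvich-style linear map of CIE XYZ referenced to the D65 white
point (`A = Y`, `T = X/Xn − Y`, `D = 0.4(Y − Z/Zn)`), so any achromatic
device series (R = G = B) maps exactly to `T = D = 0`. The colour matching
functions are the CIE 1931 2° observer, represented by the standard
multi-lobe Gaussian fit tabulated at 5 nm with linear interpolation; its
`ybar` component doubles as the photopic luminous efficiency curve
V(λ). Device rendering goes through a parametric display model (sRGB
primaries, gamma 2.2, 180 cd/m² peak white by default — the peak is chosen
to exceed the brightest battery background of 160 cd/m²); the display is a
swappable argument everywhere, since real experiments calibrate real
monitors. Out-of-gamut pixels are clipped with a warning and the clipped
fraction is reported, because the strongly saturated chromatic backgrounds
can exceed an sRGB gamut.

Geometry defaults to a 2° visual field sampled at 64 samples/degree
(128×128 images, Nyquist 32 cycles/degree).

## The ten batteries

| Property | Battery | Abscissa | Adaptor |
|---|---|---|---|
| 1 | quasi-monochromatic patches | wavelength | — |
| 2 | luminance / chromatic patches | test level | background level |
| 3–4 | fixed-contrast noise probes | frequency | — |
| 5 | delta probes; adapted CSF probes | position / frequency | adaptor frequency |
| 6–7 | Gabors in isolation | contrast | (frequency labels curves) |
| 8 | Gabor/noise tests on same-band noise | contrast | mask contrast |
| 9 | Gabor tests on other-frequency noise | contrast | \|log₂(f_mask/f_test)\| |
| 10 | Gabor tests on rotated noise | contrast | orientation difference |

Printed study conditions are baked into the defaults: brightness tests span
[0.5, 120] cd/m² on [1, 160] cd/m² backgrounds; chromatic deviations reach
±20 tristimulus units; CSF probes share C_RMSE = 0.05; the energy-masking
demo uses 4 cpd test noise with test contrasts in [0, 0.3] and mask
contrasts in [0, 0.25]; orientation masking uses 6 cpd horizontal Gabors at
50 cd/m² on 0.2-contrast masks.

Choices the figures do not dimension are package defaults: square test
patches covering 1/3 of the field side; 1-octave noise bandwidth with a
±15° angular band for oriented noise; Gabor envelope sigma 0.25°;
chromatic backgrounds at ±10 and ±20 units plus neutral.

**Contrast convention.** `C_RMSE` is the population standard deviation of
the pattern divided by the mean luminance. For full-field patterns it is
taken over the whole image; for spatially windowed tests (Gabors, noise
patches) it is taken over the envelope support (within 2σ), so that the
nominal contrast describes the local modulation rather than being diluted
by the empty surround — the masking batteries would otherwise compare
locally mismatched test and mask amplitudes. Either way, stimuli are
renormalized after synthesis so the realized contrast equals the nominal
value to 10⁻⁶.

**Composition.** Test and mask modulations add on the shared pedestal and
the composite is *not* renormalized: masking experiments require the mask
statistics to be unchanged by the test. Masking batteries carry several
mask realizations per condition (3 by default), with the *same* seed set
reused — contrast-scaled, band-shifted or rotated — across the adaptor
levels of a family: visibilities are averaged over realizations, and the
pairing keeps realization noise from confounding the curve ordering.
Noise stimuli are deterministic functions of their integer seed.

**Mask frequency sets.** The frequency cross-masking battery uses one-sided
sets toward higher frequencies (e.g. test 3 cpd → masks {3, 6, 12, 24};
test 12 cpd → {12, 17, 24}). Two-sided sets would create tied
\|log₂\| distances, and low-frequency masks carry a contrast-sensitivity
amplitude advantage that systematically reverses the proximity ordering in
any CSF-weighted observer.

## The read-out

`compute_visibility()` implements the distance read-out: the Minkowski-p
norm (p = 2, Euclidean, by default) of the difference between the
activations to test-plus-background and to the background alone, at a named
layer. All layer elements enter the norm equally; an optional spatial
window restricts it to the test support. Noise-probe measurements average
several realizations (5 by default) and report the seed count.

Two deliberate exceptions:

* **Spectral sensitivities** use a signed mean-response read-out at the
  model's first layer, where opponent channels are interpretable; a norm
  would fold the opponent valence curves.
* **Adaptation curves (property 2)** also use the signed patch-mean
  read-out, at the model's brightness layer when it exposes one. A
  distance read-out is anchored at the background (the zero-test item) and
  folds at the test = background crossing, which scrambles the known
  ordering of the curves for *any* model; the signed response does not.
  Chromatic families are evaluated along their own axis direction
  (response projected onto the family sign) for the same reason: with
  tests opposite to the background, chromatic induction legitimately
  reverses the signed ordering, so the rank is only well defined on the
  adapted side.

## Ground truth and templates

Quantitative references are packaged constants with the field's standard
shapes: V(λ) and the opponent valence curves (the opponent transform of the
colour matching functions); a band-pass achromatic CSF `(f/4)·exp(1 − f/4)`
peaking at 4 cpd with sensitivity extending past 32 cpd; low-pass chromatic
CSFs with ~15 cpd cut-offs scaled below the achromatic peak; and
Naka--Rushton saturating contrast responses (`c²/(c² + 0.1²)`) scaled per
frequency by the CSFs. They are deliberately parametric: the exact human
tables behind the published figures are not printed, so the package ships
documented standards that users can replace via the CSV import/export
(`write_ground_truth_csv()` / `read_ground_truth_csv()`).

Rank templates encode the qualitative knowledge: weaker adaptors give
higher curves (property 2); response scales follow the CSF across frequency
(property 7); curves descend with mask contrast (8), with mask–test
frequency proximity (9), and with mask–test alignment (10), the orthogonal
mask always first.

## Scoring

* **Grouped Pearson** concatenates all curves of a group into one vector
  pair before correlating, so a single global scale is forgiven but wrong
  *relative* scales (e.g. chromatic responses too strong relative to
  achromatic) are punished. Predictions are linearly interpolated onto the
  truth abscissa; points outside the predicted range are dropped and
  counted, never extrapolated. Zero-variance predictions score `NA` with a
  diagnostic reason rather than a silent 0.
* **Kendall curve rank** interpolates every curve of a family at five
  abscissa positions (evenly spaced over the upper 80% of the range, since
  near-zero responses produce degenerate ranks) and averages the tie
  corrected tau-b between observed values and the template order. Values
  within 10⁻⁸ of each other (relative to the largest curve value) are
  treated as tied: numerically coincident curves — a linear model on a
  masking battery — must score 0, not pick up systematic rounding noise.
* **Aggregate** is the plain arithmetic mean ± population standard
  deviation of the flat descriptor list, with the inclusion list recorded;
  a seeded bootstrap percentile interval quantifies how much the global
  score depends on that (arguable) selection. Two-sample KS (`ks.test`,
  exact p where feasible) compares two models' descriptor lists.

## Reference models

`linear_control()` — opponent planes through a fixed low-pass filter — is
the negative control: superposition holds exactly, so it shows no
adaptation, flat masking families (hence tau ≈ 0 through the tie rule), and
its CSF is just its filter. `identity_model()` is the trivial adapter used
by the oracles.

`toy_cascade()` is the positive control: four linear+nonlinear stages.
(1) Opponent representation with divisive luminance/chromatic gain
(response divided by a semi-saturation constant plus the background mean),
plus an explicit saturating brightness sub-layer (Naka--Rushton with
background-tied semi-saturation) exposed for the signed adaptation
read-out. (2) Contrast: deviation from the local mean (Gaussian, 0.5°)
scaled by the global mean response. (3) CSF filtering per channel using the
packaged parametric sensitivities. (4) A Gabor bank (frequencies 1.5–24
cpd in octaves, 6 orientations) with divisive normalization
`y = sign(x)·|x|^γ / (b + Σ H·|x̃|^γ)`, where `|x̃|` is the quadrature
envelope (phase-insensitive energy) and H a separable Gaussian pool over
space (0.1°), log-frequency (0.35 octave) and orientation (12°).

Two numerical choices matter and were made deliberately:

* **γ = 1 (amplitude normalization).** With a Euclidean distance read-out,
  a γ = 2 numerator produces *facilitation* whenever the local test
  amplitude exceeds the mask's: the cross term `2tm` in
  `|t+m|² − |m|²` grows faster than the pool. With γ = 1 the numerator is
  linear, masking is purely divisive, and the b→∞ limit reduces exactly to
  a linear model (masking families collapse). γ remains a configuration
  parameter.
* **Quadrature-envelope pool.** Pooling the rectified even-filter response
  makes the denominator oscillate with the carrier phase and couples test
  and mask incoherently; the envelope is smooth and monotone in mask
  contrast.

The cascade is illustrative — tuned only so that its curve shapes and
orderings are qualitatively human — and is not a reproduction of any
trained published model. `intervene_dn_constant()` scales `b` alone:
larger b flattens the nonlinearity (shallower contrast responses), smaller
b sharpens it (earlier saturation), which is the kind of targeted
intervention an interpretable parametric model affords.

## What the synthetic conditions do and do not show

Everything here is synthetic and calibrated, which is the point: the
batteries probe model behavior under exactly controlled luminance, colour,
frequency and orientation content. Passing them shows that a model's
response geometry is ordered like human low-level vision. It does not show
performance on natural images, temporal/motion properties (not generated),
dichoptic effects, or quantitative threshold prediction — the ground-truth
curves are standard shapes, not individual-observer data, and Pearson
scores against them are shape-and-relative-scale comparisons only.

## Problem sizes and determinism

The bundled evaluation profile (`profile = "quick"`) uses 8–10 frequencies,
4–5 levels per grid and 2 noise seeds per probe (~300 battery items per
model); `profile = "full"` uses the figure-level grids. All randomness
(noise realizations, bootstrap) flows from integer seeds through a private
RNG stream, so batteries, curves and reports are bit-reproducible; battery
directories store a JSON manifest with the display model, geometry and
per-plane quantization so nothing about the calibration is implicit.

Known limitations: the opponent matrix and ground-truth tables are
packaged standards, not the (unpublished) calibrations behind the original
figures; property-2 rank templates cannot distinguish any two models whose
signed responses are monotone in the adaptor (the known human *slope*
changes — crispening — would, but shape descriptors are out of scope);
cross-frequency masking of high-frequency tests is weakly resolved at this
field size, because masks above the test frequency carry little
contrast-sensitivity weight, so that family's rank score has the largest
realization variance of the battery; and 16-bit quantization bounds the
fidelity of serialized stimuli at ~1.5·10⁻⁵ of each plane's range.
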