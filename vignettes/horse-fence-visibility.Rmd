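---
title: "Modelling fence visibility to horse vision: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling fence visibility to horse vision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equisight)
```

## The model

Horses are dichromats with cone classes peaking at 428 nm (SW) and
539 nm (LW). `equisight` predicts the discriminability of fence
components from their surrounds with the log-linear receptor-noise-
limited (RNL) model. For two stimuli with quantum catches $Q_i^a,
Q_i^b$ the log signal differences are $\Delta f_i = \ln Q_i^a - \ln
Q_i^b$, and for a dichromat

$$\Delta S = \frac{|\Delta f_{LW} - \Delta f_{SW}|}
                  {\sqrt{e_{LW}^2 + e_{SW}^2}}, \qquad
  \Delta L = \frac{|\Delta f_{lum}|}{\omega_{lum}},$$

with per-receptor noise $e_i = \omega\sqrt{\eta_{max}/\eta_i}$ anchored
to the most abundant cone. The general $n$-receptor quadratic form is
implemented for completeness and cross-checked against the dichromat and
trichromat closed forms in the tests. Units are just-noticeable
differences (JNDs): values under 1 are classed *low* contrast, 1–3
*poor*, above 3 *good*; we close both boundaries on the "poor" side
(exactly 1 and exactly 3 are "poor"), consistent with bands worded as
"under 1" and "over 3".

Assumptions worth stating explicitly: discrimination is photopic and
noise-limited (no spatial acuity or viewing-distance effects — horses'
lower acuity is out of scope), catches are von Kries-adapted to the
scene illuminant, and region mean catches (not per-pixel JND averages)
enter the comparison, matching the region-measurement workflow. A
pixel-wise mode can be had by calling `jnd_result()` on pixel pairs.

### Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| SW, LW peak | 428, 539 nm | horse cone sensitivities (A1 pigment template) |
| $\omega$ | 0.05 | Weber fraction of the abundant (LW) cone |
| LW:SW abundance | 40:5 | sets $e_{SW} = 0.05\sqrt{8} \approx 0.1414$; chromatic denominator 0.15 |
| luminance channel | LW | configurable to the summed SW+LW catch |
| grid | 400–700 nm, 1 nm | rectangle-rule integration throughout |

Receptor sensitivities use the Govardovskii A1 visual-pigment template
(alpha plus beta band), parameterized only by the printed peak
wavelengths and normalized to 1; ocular-media transmission is folded
into the template rather than modelled separately, because only the
peaks are reliably published. The luminance channel is LW alone by
default — the conventional dichromat achromatic channel — since the
source workflow computes luminance JNDs from the cone data with Weber
fraction 0.05 without stating the channel composition.

## From camera counts to cone catches

The calibration chain mirrors field practice with in-frame standards:

1. **Linearize**: stored counts are inverted through the camera's
   power-law response, $x = (c/c_{max})^\gamma$, with saturation flagged
   at 99.5 % of full scale.
2. **Equalize**: per channel, the affine map sending the black and white
   PTFE standard region means to 4.49 % and 93.1 % is applied to every
   pixel. Using both standards (offset + gain) rather than gain only
   makes the result exact under any global exposure change; two points
   determine the affine map, and the workflow carries two standards.
3. **Map to cone catches**: a per-receptor polynomial regression
   (degree 2 with interactions, 10 terms over 3 channels) of direct
   spectral catches on camera values, trained per illuminant class on
   500 smooth random reflectance spectra, with a 20 % held-out split
   reported. Negative predictions are floored at $10^{-6}$ (catches are
   logged downstream) and the floored count is reported.

### The test-bench camera

Real camera dye sensitivities are proprietary, so the package ships a
synthetic test-bench camera. Its three channels are pigment-template
curves peaking at 428, 539 and 600 nm, mixed by a fixed invertible
matrix so each channel looks like an ordinary broad blue/green/red dye
curve. The deliberate consequence is that the horse SW and LW
sensitivities lie in the linear span of the channel set, which makes the
camera-to-cone mapping well-posed: no reflectance is metameric for the
camera but not for the horse. We chose this over generic Gaussian
channels after measuring the alternative: Gaussian channels at
460/530/600 nm leave more than half of the SW sensitivity outside the
channel span, which caps any polynomial mapping far below the accuracy
this workflow is predicated on (near-exact cone-catch prediction). The
span property is a statement about the *simulated* world: it encodes the
assumption that the real calibrated-camera workflow predicts catches
accurately, and confines the package's claims to pipelines where that
holds. Channel count, shapes and $\gamma$ are all configurable in
`camera_model()` for studying miscalibrated cameras.

## Light classes and the synthetic scenes

Scenes are stratified into eight classes: {Sunny, Sunny with cloud,
Overcast, Shade} × {Daytime, Evening}. No spectra are published for
these, so each class gets a smooth three-parameter daylight-family curve
$I(\lambda) = A\,(1 + t\,s + c\,(s^2 - \tfrac13))$, $s =
(\lambda-550)/150$: neutral for sunny daytime, blue-tilted for shade
(skylight), warm-tilted for evening, reduced amplitude for overcast and
evening. A seeded jitter option emulates within-class variation.

**Shade needs one extra ingredient.** Calibrated images are equalized to
in-scene standards, which is a von Kries normalization — so a uniform
change of illuminant amplitude over the whole scene cancels *exactly*
and cannot change any JND. What makes shaded fences different in the
field is that the fence stands in its own shadow (sun behind the fence)
while the foreground and the standards are in ambient light. The
generator models this with a fence-region illumination factor (0.6 for
the two shade classes) applied to the fence body, board, midrail and
patches only. Chromatic JNDs are untouched (the factor cancels in the
log differences); luminance contrasts of bright markers against turf
drop, which is exactly the field observation. A full cast-shadow
geometry is out of scope.

Materials come from a documented parametric registry (Gaussian
chlorophyll bump for turf, rising logistic for birch, steep long-pass
logistics for orange paint and yellow card, short-wave Gaussians for the
blues, flat curves for EVA and the PTFE standards, a blued ramp for
sky). These are realistic synthetic stand-ins, not measurements — none
are published for the actual materials. Fluorescence is modelled as an
illuminant-dependent radiance factor: illuminant power below 480 nm
pumps a Gaussian emission band at 530 nm, capped at a total factor of
1.5; bluer light yields a larger boost. Gloss is an additive 8 %
illuminant-coloured specular fraction.

The render path integrates radiance through the camera channels, scales
exposure so the white standard sits at 85 % of full scale, applies the
power-law response, adds seeded Gaussian read noise (default 50 counts
at 16 bit, a typical RAW sensor read noise at that scale), and
quantizes. The ground-truth layer computes every region's adapted cone
catches and pairwise JNDs purely spectrally — never through the camera —
so the full pipeline can be held to an oracle.

### What the generator does and does not emulate

It reproduces the photographic protocol's logic: in-frame standards,
region measurement, per-class illumination, marker materials,
fluorescence, fence self-shading. It does not model 3-D geometry,
perspective, cast shadows, mutual illumination, vegetation texture,
within-region material variability, or spatial acuity. Passing the
oracle-equivalence tests therefore shows the *computational chain* is
faithful; it does not validate the registry spectra against real
materials, and absolute JND values for real fences will differ.

## Numerical choices

- Integration: rectangle rule on the 1 nm grid; the test oracle is an
  independent naive summation of the same quadrature.
- Spectra CSV ingestion resamples by linear interpolation; extrapolation
  beyond a 5 nm guard band is an error.
- Training spectra are squashed into (0, 1) by a logistic rather than
  hard-clipped: clipping plateaus destroy the library's documented
  smoothness (lag-10 nm autocorrelation > 0.9). Rare near-cancelling
  draws below 0.95 are redrawn; the generator remains deterministic
  given its seed.
- Agreement between pipeline and spectral truth is judged relatively for
  supra-threshold contrasts and absolutely (denominator floored at
  1 JND) for sub-threshold ones: the relative error of any noisy
  estimate diverges as the true contrast approaches zero, while an
  absolute error well under one threshold step is perceptually
  irrelevant on both sides.
- Mapping fits use QR least squares; rank deficiency (e.g. all-identical
  training spectra) is an explicit error, as is a training set smaller
  than 10 spectra per coefficient.

Problem sizes throughout (96×128 px scenes, 500 training spectra, 100
noise seeds for the scale-calibration study) were chosen as the smallest
at which the sampling-theory checks are stable; all statistics scale up
unchanged.

## Jump kinematics

The eleven parameters are pure plane geometry on labelled keypoints:
Euclidean hoof-to-fence-base distances (anterior base at takeoff,
posterior at landing), the takeoff angle between the dorsum line (from
the croup/sacral midpoint towards the withers) and the ground line, the
interior hindquarters–withers–ears angle at the withers (bascule), the
vertical withers-to-fence-top offset, and the hind-leading-takeoff to
front-trailing-landing distance. Scale comes from the fence bars:
`spacing / mean adjacent pixel distance`, with collinearity of the bar
points checked. Two assumptions are explicit: the camera is level and
perpendicular to the fence, so the ground line defaults to the image
horizontal (a two-point ground line can be supplied); and the physical
bar spacing has *no* default — it is course furniture the user must
know. Lens-distortion correction is assumed done upstream. A synthetic
jump generator with exact truth backs the round-trip tests; under 1 px
annotation noise, distances degrade by ~30 mm worst-case and angles by
well under a degree.

## Known limitations

- Dichromat-first design: the $n$-receptor quadratic form is present,
  but no UV channel or tetrachromat conveniences.
- One mapping per illuminant class; cross-class application is allowed
  with a warning, not silently.
- The registry spectra and the gloss/fluorescence models are stand-ins;
  conclusions about specific commercial paints require measured spectra
  (which `read_spectrum_csv()` accepts directly).
- Mesopic/rod vision, acuity filtering and viewing distance are not
  modelled; JNDs here are best-case photopic discriminability.
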