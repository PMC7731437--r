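---
title: "Methods: threshold extraction of green and standing dead cover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threshold extraction of green and standing dead cover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadcover)
```

## The problem

Grassland monitoring needs per-quadrat fractional cover of two canopy
components: green vegetation (GV — photosynthetically active grasses,
forbs and shrub leaves) and standing dead matter (SDM — senesced
vegetation still upright in the canopy). Visual estimation is subjective
and tends to overestimate both; `quadcover` implements a semi-automated,
reproducible alternative that classifies every pixel of a nadir quadrat
photograph using two simple spectral rules, then counts pixels.

The method is *semi*-automated on purpose: the two GV thresholds and the
SDM brightness multiplier are human-chosen constants with sensible
defaults, not fitted parameters. The package supplies the tooling a field
scientist needs around that choice — batch processing, threshold
exploration over reference pixels, sensitivity sweeps, and validation
against spectral indices.

## Preprocessing: per-band standardization and 10-bit rescaling

Lighting differs between plots and days. To bring every image onto a
common scale, each of the three bands of each image is handled
independently:

1. **Standardize**: subtract the band mean and divide by the band
   standard deviation (population form, dividing by the pixel count N —
   deterministic, and indistinguishable from the sample form at image
   sizes).
2. **Rescale**: map the standardized band linearly onto $[0, 1023]$, so
   the band minimum becomes exactly 0 and the maximum exactly 1023.

Both statistics are per band *of one image* (computed after any crop):
each photograph is independently brought to the common 10-bit scale,
which is what makes fixed thresholds transferable across images taken
under different light.

Two numerical points. First, the composition of an affine z-score with a
min–max rescale means the whole chain is invariant under any positive
affine change of the raw digital numbers — exposure offset and gain
cancel exactly (a tested property). Second, the rescale divides before
multiplying by 1023, which keeps the ratio inside $[0, 1]$ in floating
point so the endpoint guarantees (`min == 0`, `max == 1023`) are exact,
not approximate. Values are kept as reals throughout — the decimal
thresholds that threshold exploration produces (e.g. 60.18) only exist if
the band differences are computed in floating point; rounding happens
only when bands are exported as 16-bit grayscale images.

A band with zero variance (a constant crop) cannot be standardized and
raises a degenerate-band error naming the band; a zero-pixel image is an
error, not 0 % cover.

## Classification rules

On the normalized scale, with bands $R, G, B$:

* **GV rule** (thresholds $g_1, g_2$, default 60 each):
  $(G - R) > g_1 \;\wedge\; (G - B) > g_2$.
  Green leaves are the only scene component whose green band dominates
  both red and blue. Both inequalities are strict; a pixel whose
  difference equals the threshold is excluded (so a difference of exactly
  60 at $g = 60$ is *not* GV).
* **SDM rule** (multiplier $d$, default 1): among pixels *not* classified
  GV, $R > d\bar R \;\wedge\; G > d\bar G \;\wedge\; B > d\bar B$, with
  $\bar R, \bar G, \bar B$ the per-band means of the normalized image.
  Standing dead material sits in the sunlit canopy and is brighter in all
  three bands than the shaded understory (litter, soil crust, bare
  soil). The means are computed over **all** pixels, before GV masking;
  GV pixels are excluded only from SDM candidacy, never from the means.
  At $d = 1$ this rule is equivalent to comparing raw digital numbers
  against their scene means, since the mean commutes with the affine
  normalization.

Precedence is GV over SDM, order of operations fixed: means, GV mask, SDM
mask on the remainder, cover. Cover is plain pixel counting divided by
the total. There is no spatial post-processing — the method is strictly
per-pixel, so covers are exactly invariant under resolution changes
(tested as block-replication invariance), and the manual 300-dpi
resampling step used in field workflows is a no-op here.

### Choosing the constants

* $g_1$ below 60 (about 30–45) recovers GV under high exposure or early
  senescence; $g_2$ near 32 recovers bluish-leaved canopies (sagebrush,
  western wheatgrass). `explore_gv_thresholds()` reports the
  min/max/mean/sd of both differences over a user-supplied reference mask
  of known-GV pixels — the minima are the candidate thresholds, since any
  value at or below the minimum keeps the whole reference inside the GV
  class. What counts as a reference region (and its condition label:
  normal light, high exposure, senesced, bluish) is the user's call, not
  inferred.
* $d < 1$ (0.5–0.7) reaches the darker, lower SDM stratum in dense dead
  canopies; $d > 1$ (1.2–2) suppresses light-colored litter, crust and
  bare soil that would otherwise pass the brightness rule. `sweep_d()`
  and `sweep_g()` trace the cover response; cover is monotone
  non-increasing in each threshold (a tested invariant), so the sweeps
  are easy to read.

## Spectral validation

Where field spectra exist, extracted covers are validated by ordinary
least squares against two indices computed from 350–2500 nm reflectance:

$$\mathrm{NDVI} = \frac{\rho_{800} - \rho_{670}}{\rho_{800} + \rho_{670}},
\qquad
\mathrm{CAI} = 100\,(0.5\,(\rho_{2030} + \rho_{2210}) - \rho_{2100}).$$

NDVI tracks green biomass; CAI measures the depth of the 2100 nm
cellulose–lignin absorption feature and tracks non-photosynthetic
vegetation (NPV). Reflectance at a named wavelength is linearly
interpolated between the bracketing samples — exact for instruments that
resample to 1 nm, and safe otherwise; whether to average a window around
each wavelength instead is an open choice, and the single-wavelength
reading was adopted for determinism. GV cover is regressed on NDVI. For
CAI the response is NPV cover = extracted SDM + *observed* litter cover
(an external input column): SDM alone is not expected to track CAI
because litter contributes to the cellulose signal but not to the
standing-canopy classification. The slope p-value is a two-sided t-test
with $n - 2$ degrees of freedom (the regression convention; the choice
was open and this is the standard one).

## The synthetic scene generator

`generate_quadrat()` builds labeled scenes from five components (gv, sdm,
litter, crust, soil): pixel counts by largest-remainder apportionment of
the requested fractions (exact whenever fraction × total is an integer),
positions by seeded shuffle (or contiguous patches for visual
inspection), colors as per-component palette means plus per-channel
Gaussian noise (default sd 8 DN, a realistic sensor/texture level for
consumer cameras), clipped to [0, 255]. Everything is deterministic given
the seed, and the global RNG state is untouched.

The default palette is *designed*, not sampled from imagery, so that the
default parameters separate the classes:

* all three understory components share a green mean of 100 DN while GV
  (160) and SDM (190) lie above it. The scene's green mean is therefore
  $\ge$ 100 whenever any canopy is present, and the strict brightness
  rule provably admits no understory pixel in the noise-free case, for
  any mixture — only SDM, the per-band maximum, passes;
* every understory component is red-dominant by at least 15–20 DN, so
  the $G - R$ half of the conjunctive GV rule holds understory roughly
  2σ below the default threshold under the default noise. Without this
  margin, near-neutral understory leaks into GV at the few-percent level
  — enough to bias recovered GV cover upward.

Scenario presets encode the method's known edge cases: `bluish` shifts
the GV blue mean up by 79 DN, placing the noise-free normalized $G - B$
difference between 32 and 60 so that the default $g_2 = 60$ misses the
canopy and the tuned $g_2 = 32$ recovers it; `dense-sdm` dims half the
SDM pixels to 0.55 of their palette color, a lower stratum only recovered
at $d < 1$; `light-litter` and `light-soil` brighten the understory so it
leaks into SDM at $d = 1$ and is suppressed at larger $d$; and
`white-flowers` recolors part of the GV class bright white — those pixels
are misclassified SDM at every $d$, which is the method's real, known
flower limitation.

`generate_spectrum()` mixes three synthetic endmembers (piecewise-linear
at 1 nm) linearly: GV with a strong red edge ($\rho_{670} = 0.05$,
$\rho_{800} = 0.5$, NDVI $\approx 0.818$) and a flat 2030–2210 nm region
(CAI exactly 0); NPV with a 2100 nm trough (CAI = 5); soil flat near both
index regions (NDVI = 0.1, CAI = 0). CAI is linear in the mixing
fractions; NDVI is a ratio but near-linear over the mixtures used, which
is why paired scenes and spectra close the validation loop with
$R^2 > 0.99$ at zero spectral noise.

### What the generator does and does not emulate

It reproduces the *decision geometry* of the method — class palettes,
brightness strata, noise, exact ground truth — but not the texture,
spatial autocorrelation, shadows, specular highlights or mixed-boundary
pixels of real photographs (the per-pixel classifier is blind to
arrangement, so this costs little). Passing the recovery suite therefore
shows the implementation is faithful and the defaults behave as designed
under controlled conditions; it does not certify accuracy on real
imagery, which is what the NDVI/CAI regression workflow is for.

One behavior deserves explicit note: on scenes with almost no canopy
(GV + SDM near zero) the green band carries almost pure noise, the
min–max rescale stretches that noise across the full 10-bit range, and
classification degrades sharply. This mirrors the real method's
limitation on vegetation-free plots and is why recovery is stated as a
rate over random mixtures rather than a uniform guarantee.

## Problem sizes and test design

The test and acceptance workloads use 100 × 100 scenes (10,000 pixels) —
large enough that largest-remainder allocation is exact at two-decimal
fractions and binomial noise in recovery rates is small, small enough to
keep the whole suite fast: 50 seeded scenes for recovery, 200 random
images up to 64 × 64 against an independent per-pixel scalar-loop
reference, 20-image × 10-point grids for monotonicity, and 20 paired
scene/spectrum quadrats for validation closure. The scalar-loop oracle is
written as naive nested loops sharing no code with the vectorized path.

## Worked example

```{r example, eval = FALSE}
library(quadcover)

quad <- generate_quadrat(scene_preset("baseline", seed = 1))
norm <- preprocess_image(quad$image)
result <- classify_image(norm, classification_params(g1 = 60, g2 = 60, d = 1))
tidy(result)

sweep_d(norm, d_values = c(0.5, 0.7, 1, 1.5, 2)) |> autoplot()

pairs <- generate_paired_set(n = 20, seed = 1, spectral_noise_sd = 0)
covers <- vapply(pairs, \(p) classify_image(preprocess_image(p$quadrat$image))$cover$gv_cover, numeric(1))
ndvis  <- vapply(pairs, \(p) ndvi(p$spectrum), numeric(1))
glance(validate_cover(covers, ndvis))
```

## Known limitations

* Vegetation-free or near-vegetation-free quadrats normalize noise up to
  full scale; covers from such images are unreliable.
* White or very pale flowers inside green canopy classify as SDM at any
  `d`; no automatic suppression is attempted.
* Green moss can satisfy the GV rule under permissive thresholds; the
  recommended response is raising `g1` relative to `g2`, guided by
  `explore_gv_thresholds()` on a moss reference region.
* The classifier is per-pixel: it cannot use shape, texture or context,
  and boundary pixels in real images are mixtures the synthetic scenes do
  not emulate.
* Thresholds are constants chosen by the analyst; the package computes
  the evidence for that choice but deliberately performs no automatic
  optimization.
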