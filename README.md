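# quadcover

Semi-automated extraction of **green vegetation (GV)** and **standing
dead matter (SDM)** fractional cover from nadir quadrat RGB photographs
of mixed grassland — canopies over a complex background of litter, soil
crust (moss and lichen), rocks and bare soil.

Field ecologists usually estimate cover visually, which is subjective
and tends to run high. `quadcover` replaces that with a reproducible
per-pixel classification that needs only three human-chosen constants,
plus the tooling around the choice: batch processing with per-image
overrides, threshold exploration over reference pixels, sensitivity
sweeps, spectral-index validation, and a synthetic scene generator with
exact ground truth for testing.

## The method

Each band of each image is independently standardized and rescaled to a
common 10-bit range:

```
DNstd = (DN - mean(DN)) / sd(DN)                      per band, per image
DNnor = 1023 * (DNstd - min) / (max - min)            so each band spans [0, 1023]
```

This cancels exposure offset and gain exactly, making fixed thresholds
transferable across images taken under different light. On the
normalized scale a pixel is

* **GV** iff `(G - R) > g1` **and** `(G - B) > g2` (strict; defaults
  `g1 = g2 = 60`) — green leaves are the only component whose green band
  dominates both red and blue;
* **SDM** iff it is not GV and `R > d*mean(R)`, `G > d*mean(G)`,
  `B > d*mean(B)` (strict; default `d = 1`, means over *all* pixels
  before GV masking) — standing dead material is sunlit and brighter
  than the shaded understory in all three bands.

Cover is pixel counting over the total. Lower `g1` (30–45) suits high
exposure and senescing canopies, lower `g2` (~32) bluish leaves
(sagebrush, western wheatgrass); `d < 1` recovers the darker lower SDM
stratum in dense dead canopies, `d > 1` suppresses light litter, crust
and soil. Extracted covers are validated by linear regression against
NDVI (GV) and the cellulose absorption index CAI (SDM + litter = NPV)
computed from field reflectance spectra:

```
NDVI = (rho800 - rho670) / (rho800 + rho670)
CAI  = 100 * (0.5 * (rho2030 + rho2210) - rho2100)
```

## Worked example

```r
library(quadcover)

quad   <- generate_quadrat(scene_preset("baseline", seed = 1))  # known truth
norm   <- preprocess_image(quad$image)
result <- classify_image(norm, classification_params(g1 = 60, g2 = 60, d = 1))
result
#> <cover result>  synthetic_seed1
#>   g1 = 60  g2 = 60  d = 1
#>   GV   31.27%  (3127 px)
#>   SDM  23.73%  (2373 px)
quad$true_fractions
#>    gv    sdm litter  crust   soil
#>  0.30   0.25   0.20   0.10   0.15
```

The extracted covers sit within ~1.3 points of the generated truth (30 %
GV, 25 % SDM) at the default noise level. Sensitivity of SDM cover to
the brightness multiplier, on the same image:

```r
sweep_d(norm, d_values = c(0.5, 0.7, 1, 1.5, 2))
#>     d sdm_cover
#> 1 0.5     31.60
#> 2 0.7     23.97
#> 3 1.0     23.73
#> 4 1.5     23.22
#> 5 2.0      0.00
```

Cover never increases with `d`; the jump below `d = 0.7` is understory
starting to pass the relaxed brightness rule. Validation closure over 20
paired synthetic scenes/spectra:

```r
pairs  <- generate_paired_set(n = 20, seed = 1, spectral_noise_sd = 0)
covers <- vapply(pairs, \(p) classify_image(preprocess_image(p$quadrat$image))$cover$gv_cover, numeric(1))
ndvis  <- vapply(pairs, \(p) ndvi(p$spectrum), numeric(1))
glance(validate_cover(covers, ndvis))
#>   r.squared  p.value slope intercept     n
#> 1     0.998 1.21e-26  139.     -14.8    20
```

Extracted GV cover tracks NDVI almost perfectly when both derive from
the same mixtures — the regression workflow one would run on field data
with `run_validation()`.

Batch processing a directory, with per-image overrides and mask export:

```r
run_batch("photos/", "covers.csv", masks_dir = "masks/",
          overrides = "overrides.csv")   # columns: filename, g1, g2, d
```

A thin command-line wrapper with subcommands `preprocess`, `classify`,
`batch`, `sweep`, `spectra`, `synth` is installed at
`inst/cli/quadcover.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "quadcover.R", package = "quadcover"))')" \
    batch --input photos/ --output covers.csv --save-masks masks/
```

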