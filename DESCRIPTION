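Package: quadcover
Title: Green and Standing Dead Cover from Quadrat RGB Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Semi-automated extraction of green vegetation and standing
    dead matter fractional cover from nadir quadrat RGB photographs of
    mixed grassland. Bands are standardized and min-max rescaled to a
    10-bit range per image; green vegetation is thresholded on the
    normalized green-red and green-blue differences and standing dead
    matter on per-band brightness relative to the scene means. Includes
    parameter-tuning sweeps, NDVI/CAI spectral-index validation against
    field reflectance spectra, a synthetic labeled-scene generator with
    known ground truth, and a batch runner with per-image overrides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    jpeg,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
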