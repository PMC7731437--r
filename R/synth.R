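# Synthetic quadrat scenes with known component fractions, and synthetic
# reflectance spectra from linear endmember mixing. These give every other
# module a testable ground truth in the absence of field data.

SCENE_COMPONENTS <- c("gv", "sdm", "litter", "crust", "soil")

#' Default component palette
#'
#' Mean RGB digital numbers per scene component. Two properties make the
#' default thresholds (g1 = g2 = 60, d = 1) separate the classes in the
#' noise-free case for any mixture, and keep them separated under
#' realistic per-channel noise:
#'
#' * the understory components (litter, crust, soil) share a green mean of
#'   100 while GV (160) and SDM (190) sit above it, so the scene's green
#'   mean exceeds the understory green level whenever any canopy is
#'   present and the strict brightness rule never admits understory;
#' * every understory component is red-dominant (red at least 15 DN above
#'   green), so the green-minus-red half of the conjunctive GV rule holds
#'   them at least about two noise standard deviations below the default
#'   threshold on the normalized scale.
#'
#' SDM is the per-band maximum, GV the red/blue minimum.
#'
#' @return Tibble with columns `component`, `r`, `g`, `b`.
#' @export
default_palette <- function() {
  tibble::tribble(
    ~component, ~r,  ~g,  ~b,
    "gv",        60, 160,  60,
    "sdm",      210, 190, 175,
    "litter",   140, 100,  95,
    "crust",    115, 100, 105,
    "soil",     125, 100,  90
  )
}

#' Specify a synthetic quadrat scene
#'
#' @param width,height scene size in pixels.
#' @param fractions named numeric over `gv`, `sdm`, `litter`, `crust`,
#'   `soil` (missing components default to 0); must sum to 1.
#' @param palette per-component mean RGB, as [default_palette()].
#' @param noise_sd per-channel Gaussian noise standard deviation in DN
#'   (default 8, a realistic sensor/texture level for field photographs).
#' @param gv_blueness DN added to the GV blue mean to emulate bluish
#'   leaves (sagebrush, western wheatgrass); reduces the G - B contrast.
#' @param gv_white_fraction fraction of GV pixels recolored bright white
#'   (flowers); their ground-truth label stays `gv`.
#' @param sdm_strata optional `list(bright_fraction=, dimming=)`: that
#'   fraction of SDM pixels keeps the full palette color, the rest is
#'   multiplied by `dimming` to emulate the darker lower canopy stratum of
#'   dense dead material.
#' @param arrangement `"scatter"` (seeded random scatter, default) or
#'   `"patch"` (contiguous row-major blocks, human-inspectable).
#' @param seed integer; the generator is deterministic given the spec.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(width, height, fractions,
                       palette = default_palette(), noise_sd = 8,
                       gv_blueness = 0, gv_white_fraction = 0,
                       sdm_strata = NULL,
                       arrangement = c("scatter", "patch"), seed = 1L) {
  arrangement <- match.arg(arrangement)
  stopifnot(width >= 1, height >= 1, noise_sd >= 0)
  fr <- stats::setNames(numeric(length(SCENE_COMPONENTS)), SCENE_COMPONENTS)
  if (is.null(names(fractions)) || !all(names(fractions) %in% SCENE_COMPONENTS)) {
    stop("`fractions` must be named over: ", paste(SCENE_COMPONENTS, collapse = ", "),
         call. = FALSE)
  }
  fr[names(fractions)] <- fractions
  if (any(fr < 0)) stop("fractions must be non-negative", call. = FALSE)
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("fractions must sum to 1 (got ", format(sum(fr)), ")", call. = FALSE)
  }
  if (!all(SCENE_COMPONENTS %in% palette$component)) {
    stop("palette must cover all five components", call. = FALSE)
  }
  if (!is.null(sdm_strata)) {
    stopifnot(is.list(sdm_strata),
              sdm_strata$bright_fraction >= 0, sdm_strata$bright_fraction <= 1,
              sdm_strata$dimming > 0, sdm_strata$dimming <= 1)
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 fractions = fr, palette = palette, noise_sd = noise_sd,
                 gv_blueness = gv_blueness, gv_white_fraction = gv_white_fraction,
                 sdm_strata = sdm_strata, arrangement = arrangement,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# largest-remainder apportionment: counts sum to total exactly and match
# round(fraction * total) whenever that is already consistent
allocate_counts <- function(fractions, total) {
  exact <- fractions * total
  base <- floor(exact)
  short <- total - sum(base)
  if (short > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

#' Generate a synthetic quadrat scene
#'
#' Pixel counts per component follow largest-remainder apportionment of
#' the requested fractions (so realized fractions are exact whenever
#' `fraction * total` is an integer); positions are a seeded shuffle (or
#' contiguous blocks under the `"patch"` arrangement); colors are the
#' component palette mean plus per-channel Gaussian noise, clipped to
#' \[0, 255\]. Deterministic given the spec's seed; the global RNG state
#' is left untouched.
#'
#' @param spec a [scene_spec()].
#' @return A `synthetic_quadrat`: list with `image` ([raw_image()]),
#'   `labels` (H x W character matrix), `true_fractions` (realized pixel
#'   fractions) and `spec`.
#' @export
generate_quadrat <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  total <- spec$width * spec$height
  counts <- allocate_counts(spec$fractions, total)
  if (any(spec$fractions > 0 & counts == 0)) {
    stop("image too small to realize every nonzero component", call. = FALSE)
  }
  withr::with_seed(spec$seed, {
    labels_vec <- rep(names(counts), counts)
    if (spec$arrangement == "scatter") labels_vec <- sample(labels_vec)
    labels <- matrix(labels_vec, nrow = spec$height, ncol = spec$width,
                     byrow = TRUE)

    pal <- spec$palette
    means <- array(0, c(spec$height, spec$width, 3))
    for (comp in SCENE_COMPONENTS) {
      sel <- labels == comp
      if (!any(sel)) next
      rgb <- as.numeric(pal[pal$component == comp, c("r", "g", "b")])
      if (comp == "gv") rgb[3] <- min(255, rgb[3] + spec$gv_blueness)
      for (ch in 1:3) {
        plane <- means[, , ch]; plane[sel] <- rgb[ch]; means[, , ch] <- plane
      }
    }
    if (!is.null(spec$sdm_strata) && counts[["sdm"]] > 0) {
      idx <- which(labels == "sdm")
      n_dark <- round((1 - spec$sdm_strata$bright_fraction) * length(idx))
      dark <- sample(idx, n_dark)
      for (ch in 1:3) {
        plane <- means[, , ch]
        plane[dark] <- plane[dark] * spec$sdm_strata$dimming
        means[, , ch] <- plane
      }
    }
    if (spec$gv_white_fraction > 0 && counts[["gv"]] > 0) {
      idx <- which(labels == "gv")
      white <- sample(idx, round(spec$gv_white_fraction * length(idx)))
      flower_rgb <- c(245, 242, 238)
      for (ch in 1:3) {
        plane <- means[, , ch]; plane[white] <- flower_rgb[ch]
        means[, , ch] <- plane
      }
    }
    px <- means + array(stats::rnorm(3 * total, sd = spec$noise_sd),
                        c(spec$height, spec$width, 3))
    px <- array(round(pmin(255, pmax(0, px))), dim(means))
  })
  realized <- table(factor(labels, levels = SCENE_COMPONENTS)) / total
  structure(
    list(image = raw_image(px, source_path = sprintf("synthetic_seed%d", spec$seed)),
         labels = labels,
         true_fractions = stats::setNames(as.numeric(realized), SCENE_COMPONENTS),
         spec = spec),
    class = "synthetic_quadrat"
  )
}

#' Scenario presets for the method's known edge cases
#'
#' * `"baseline"`: mixed scene, default palette.
#' * `"bluish"`: GV blue mean shifted up so default `g2 = 60` misses the
#'   canopy while the tuned `g2 = 32` recovers it.
#' * `"dense-sdm"`: two SDM brightness strata; the dark lower stratum is
#'   only recovered at `d < 1`.
#' * `"light-litter"` / `"light-soil"`: brightened understory that leaks
#'   into SDM at `d = 1` and is suppressed at `d > 1`.
#' * `"white-flowers"`: bright white blobs inside the GV class that no
#'   `d` can exclude from SDM.
#'
#' @param name preset name.
#' @param width,height scene size.
#' @param seed integer seed.
#' @return A [scene_spec()].
#' @export
scene_preset <- function(name = c("baseline", "bluish", "dense-sdm",
                                  "light-litter", "light-soil", "white-flowers"),
                         width = 100, height = 100, seed = 1L) {
  name <- match.arg(name)
  base_fr <- c(gv = 0.3, sdm = 0.25, litter = 0.2, crust = 0.1, soil = 0.15)
  pal <- default_palette()
  switch(name,
    "baseline" = scene_spec(width, height, base_fr, seed = seed),
    "bluish" = scene_spec(width, height, base_fr, gv_blueness = 79, seed = seed),
    "dense-sdm" = scene_spec(
      width, height, c(gv = 0.1, sdm = 0.6, litter = 0.1, crust = 0.1, soil = 0.1),
      sdm_strata = list(bright_fraction = 0.5, dimming = 0.55), seed = seed),
    "light-litter" = {
      pal[pal$component == "litter", c("r", "g", "b")] <- list(185, 160, 150)
      scene_spec(width, height,
                 c(gv = 0.2, sdm = 0.3, litter = 0.3, crust = 0.1, soil = 0.1),
                 palette = pal, seed = seed)
    },
    "light-soil" = {
      pal[pal$component == "soil", c("r", "g", "b")] <- list(160, 150, 140)
      scene_spec(width, height,
                 c(gv = 0.2, sdm = 0.2, litter = 0.1, crust = 0.1, soil = 0.4),
                 palette = pal, seed = seed)
    },
    "white-flowers" = scene_spec(width, height, base_fr,
                                 gv_white_fraction = 0.15, seed = seed)
  )
}

#' Write a synthetic scene to disk
#'
#' Image as RGB PNG, labels as an 8-bit grayscale PNG of component codes
#' (0 = gv, 1 = sdm, 2 = litter, 3 = crust, 4 = soil), and a JSON sidecar
#' with the true fractions and the generating parameters.
#'
#' @param quad a [generate_quadrat()] result.
#' @param dir output directory.
#' @param stem filename stem.
#' @return Invisibly, the written paths.
#' @export
write_scene <- function(quad, dir, stem = "scene") {
  stopifnot(inherits(quad, "synthetic_quadrat"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  img_path <- file.path(dir, paste0(stem, ".png"))
  png::writePNG(unclass(quad$image) / 255, img_path)
  lab_path <- file.path(dir, paste0(stem, "_labels.png"))
  codes <- matrix(match(quad$labels, SCENE_COMPONENTS) - 1L,
                  nrow(quad$labels), ncol(quad$labels))
  png::writePNG(codes / 255, lab_path)
  json_path <- file.path(dir, paste0(stem, ".json"))
  sp <- quad$spec
  jsonlite::write_json(
    list(true_fractions = as.list(quad$true_fractions),
         width = sp$width, height = sp$height, seed = sp$seed,
         noise_sd = sp$noise_sd, arrangement = sp$arrangement,
         fractions = as.list(sp$fractions)),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(image = img_path, labels = lab_path, sidecar = json_path))
}

# --- synthetic spectra ------------------------------------------------------

# endmember control points; linear interpolation to 1 nm. The 2030-2210
# segment is constant for gv and soil (CAI exactly 0) and shows a 2100 nm
# trough for npv (CAI = 5). rho670/rho800 give NDVI 0.818 (gv), 0.123
# (npv), 0.100 (soil).
endmember_points <- function() {
  list(
    gv = cbind(c(350, 500, 550, 650, 670, 700, 750, 800, 900, 1300, 1450,
                 1650, 1900, 2030, 2210, 2350, 2500),
               c(0.04, 0.06, 0.12, 0.06, 0.05, 0.12, 0.42, 0.50, 0.50, 0.45,
                 0.28, 0.32, 0.14, 0.20, 0.20, 0.12, 0.10)),
    npv = cbind(c(350, 550, 670, 800, 1300, 1900, 2030, 2100, 2210, 2350, 2500),
                c(0.08, 0.15, 0.25, 0.32, 0.38, 0.30, 0.32, 0.25, 0.28, 0.26, 0.24)),
    soil = cbind(c(350, 670, 800, 1300, 1900, 2030, 2210, 2500),
                 c(0.10, 0.225, 0.275, 0.30, 0.27, 0.26, 0.26, 0.24))
  )
}

#' Synthetic endmember spectra
#'
#' Three idealized pure-component spectra sampled at 1 nm over
#' 350--2500 nm: green vegetation (strong red-edge, no 2100 nm trough),
#' non-photosynthetic vegetation (2100 nm cellulose trough between the
#' 2030/2210 shoulders) and soil (spectrally flat near both index
#' regions).
#'
#' @return Named list of [spectrum()] objects: `gv`, `npv`, `soil`.
#' @export
endmember_spectra <- function() {
  wl <- 350:2500
  lapply(endmember_points(), function(pts) {
    spectrum(wl, stats::approx(pts[, 1], pts[, 2], xout = wl)$y)
  })
}

#' Generate a synthetic mixed reflectance spectrum
#'
#' Linear mixture of the three endmembers plus (optionally) small seeded
#' Gaussian noise, clipped to \[0, 1\].
#'
#' @param gv_fraction,npv_fraction,soil_fraction non-negative, sum to 1.
#' @param seed integer seed for the noise (ignored when `noise_sd = 0`).
#' @param noise_sd reflectance noise standard deviation (default 0.002).
#' @return A [spectrum()] at 1 nm over 350--2500 nm.
#' @export
generate_spectrum <- function(gv_fraction, npv_fraction, soil_fraction,
                              seed = 1L, noise_sd = 0.002) {
  fr <- c(gv_fraction, npv_fraction, soil_fraction)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    stop("fractions must be non-negative and sum to 1", call. = FALSE)
  }
  stopifnot(noise_sd >= 0, noise_sd <= 0.002)
  em <- endmember_spectra()
  refl <- fr[1] * em$gv$reflectance + fr[2] * em$npv$reflectance +
    fr[3] * em$soil$reflectance
  if (noise_sd > 0) {
    refl <- withr::with_seed(as.integer(seed),
                             refl + stats::rnorm(length(refl), sd = noise_sd))
  }
  spectrum(350:2500, pmin(1, pmax(0, refl)))
}

#' Generate paired scenes and spectra with shared fractions
#'
#' For validation closure: each quadrat gets a scene (image ground truth)
#' and a spectrum mixed from the same fractions, with the spectral NPV
#' fraction equal to the scene's SDM + litter share and the spectral soil
#' fraction absorbing crust + soil.
#'
#' @param n number of quadrats.
#' @param width,height scene size.
#' @param seed integer master seed.
#' @param noise_sd scene DN noise.
#' @param spectral_noise_sd spectrum reflectance noise.
#' @return List of `n` elements, each `list(quadrat=, spectrum=)`.
#' @export
generate_paired_set <- function(n = 20, width = 80, height = 80, seed = 1L,
                                noise_sd = 8, spectral_noise_sd = 0) {
  seeds <- seed + seq_len(n) - 1L
  lapply(seq_len(n), function(i) {
    fr <- withr::with_seed(seeds[i] + 10000L, {
      u <- stats::runif(5, 0, 0.6)
      stats::setNames(u / sum(u), SCENE_COMPONENTS)
    })
    quad <- generate_quadrat(scene_spec(width, height, fr,
                                        noise_sd = noise_sd, seed = seeds[i]))
    tf <- quad$true_fractions
    spec <- generate_spectrum(tf[["gv"]], tf[["sdm"]] + tf[["litter"]],
                              tf[["crust"]] + tf[["soil"]],
                              seed = seeds[i], noise_sd = spectral_noise_sd)
    list(quadrat = quad, spectrum = spec)
  })
}
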