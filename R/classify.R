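# GV / SDM threshold classification and fractional cover.
#
# On the normalized 0-1023 scale a pixel is green vegetation (GV) when its
# green band exceeds red by more than g1 AND exceeds blue by more than g2
# (strict). Remaining pixels are standing dead matter (SDM) when all three
# bands exceed d times the per-band scene mean (strict); the means are
# taken over ALL pixels, before GV masking. Everything else is "other"
# (litter, soil crust, bare soil, rock).

#' Classification parameters
#'
#' @param g1 threshold on the normalized green-minus-red difference
#'   (default 60). Values down to about 30 are used for high-exposure or
#'   senesced scenes; negative values are permitted.
#' @param g2 threshold on the normalized green-minus-blue difference
#'   (default 60; around 32 for bluish-leaved canopies such as sagebrush
#'   and western wheatgrass).
#' @param d multiplier on the per-band scene means in the SDM brightness
#'   rule (default 1). Lower values (0.5--0.7) recover the darker lower
#'   SDM stratum in dense dead canopies; higher values (1.2--2) suppress
#'   light litter, crust and bare soil.
#' @return A `classification_params` list.
#' @export
classification_params <- function(g1 = 60, g2 = 60, d = 1) {
  if (!is.finite(g1) || !is.finite(g2)) stop("g1 and g2 must be finite", call. = FALSE)
  if (!is.finite(d) || d <= 0) stop("d must be a positive number", call. = FALSE)
  structure(list(g1 = g1, g2 = g2, d = d), class = "classification_params")
}

#' Green-vegetation mask
#'
#' A pixel is GV iff (G - R) > g1 and (G - B) > g2, both strict, on the
#' normalized scale.
#'
#' @param norm a `quad_norm` image.
#' @param g1,g2 thresholds, see [classification_params()].
#' @return Logical matrix, `TRUE` for GV pixels.
#' @export
classify_gv <- function(norm, g1 = 60, g2 = 60) {
  stopifnot(inherits(norm, "quad_norm"))
  (norm$g - norm$r > g1) & (norm$g - norm$b > g2)
}

#' Per-band means of a normalized image
#'
#' Arithmetic means over all pixels of each band, including pixels later
#' classified as GV: the SDM brightness reference is the whole scene, not
#' the GV-masked remainder.
#'
#' @param norm a `quad_norm` image.
#' @return Named numeric vector `c(r=, g=, b=)`.
#' @export
band_means <- function(norm) {
  stopifnot(inherits(norm, "quad_norm"))
  c(r = mean(norm$r), g = mean(norm$g), b = mean(norm$b))
}

#' Standing-dead-matter mask
#'
#' Among non-GV pixels, a pixel is SDM iff every band strictly exceeds `d`
#' times that band's scene mean.
#'
#' @param norm a `quad_norm` image.
#' @param gv_mask logical matrix from [classify_gv()].
#' @param means named vector from [band_means()].
#' @param d brightness multiplier, `> 0`.
#' @return Logical matrix, `TRUE` for SDM pixels; never overlaps `gv_mask`.
#' @export
classify_sdm <- function(norm, gv_mask, means = band_means(norm), d = 1) {
  stopifnot(inherits(norm, "quad_norm"))
  if (!identical(dim(gv_mask), dim(norm$r))) {
    stop("`gv_mask` shape does not match the image", call. = FALSE)
  }
  if (d <= 0) stop("d must be positive", call. = FALSE)
  bright <- (norm$r > d * means[["r"]]) &
            (norm$g > d * means[["g"]]) &
            (norm$b > d * means[["b"]])
  bright & !gv_mask
}

#' Bundle GV/SDM/other masks
#'
#' @param gv,sdm logical matrices of equal dimension; must be disjoint.
#' @return A `class_masks` object with the complementary `other` mask.
#' @export
class_masks <- function(gv, sdm) {
  if (!identical(dim(gv), dim(sdm))) stop("mask shapes differ", call. = FALSE)
  if (any(gv & sdm)) stop("GV and SDM masks overlap", call. = FALSE)
  structure(list(gv = gv, sdm = sdm, other = !(gv | sdm)), class = "class_masks")
}

#' Fractional cover from class masks
#'
#' @param masks a [class_masks()] object.
#' @return One-row tibble: `total_pixels`, `gv_pixels`, `sdm_pixels`,
#'   `gv_cover`, `sdm_cover` (percent of total pixels).
#' @export
compute_cover <- function(masks) {
  stopifnot(inherits(masks, "class_masks"))
  total <- length(masks$gv)
  if (total == 0L) stop("zero-pixel image has no defined cover", call. = FALSE)
  gv <- sum(masks$gv)
  sdm <- sum(masks$sdm)
  tibble::tibble(
    total_pixels = total, gv_pixels = gv, sdm_pixels = sdm,
    gv_cover = 100 * gv / total, sdm_cover = 100 * sdm / total
  )
}

#' Classify a normalized image and compute cover
#'
#' Fixed order of operations: per-band scene means first, then the GV
#' rule, then the SDM rule on the GV-masked image, then cover.
#'
#' @param norm a `quad_norm` image.
#' @param params a [classification_params()] object.
#' @return A `cover_result`: list with `masks` ([class_masks()]), `cover`
#'   (one-row tibble), `params`, `source`.
#' @export
classify_image <- function(norm, params = classification_params()) {
  stopifnot(inherits(norm, "quad_norm"), inherits(params, "classification_params"))
  means <- band_means(norm)
  gv <- classify_gv(norm, params$g1, params$g2)
  sdm <- classify_sdm(norm, gv, means, params$d)
  masks <- class_masks(gv, sdm)
  structure(
    list(masks = masks, cover = compute_cover(masks), params = params,
         band_means = means, source = attr(norm, "source")),
    class = "cover_result"
  )
}

#' @export
print.cover_result <- function(x, ...) {
  cat("<cover result>")
  if (!is.na(x$source %||% NA)) cat(" ", x$source)
  cat("\n  g1 =", x$params$g1, " g2 =", x$params$g2, " d =", x$params$d, "\n")
  cat(sprintf("  GV  %6.2f%%  (%d px)\n", x$cover$gv_cover, x$cover$gv_pixels))
  cat(sprintf("  SDM %6.2f%%  (%d px)\n", x$cover$sdm_cover, x$cover$sdm_pixels))
  invisible(x)
}

#' @rdname classify_image
#' @param x a `cover_result`.
#' @param ... unused.
#' @method tidy cover_result
#' @export
tidy.cover_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(image = x$source %||% NA_character_),
    x$cover,
    tibble::tibble(g1 = x$params$g1, g2 = x$params$g2, d = x$params$d)
  )
}

#' Export class masks as an 8-bit grayscale PNG of class codes
#'
#' Pixel values are the class codes themselves: 0 = other, 1 = GV,
#' 2 = SDM. The values, not the display colors, are the contract.
#'
#' @param masks a [class_masks()] object.
#' @param path output .png path.
#' @return Invisibly, `path`.
#' @export
write_mask_png <- function(masks, path) {
  stopifnot(inherits(masks, "class_masks"))
  codes <- matrix(0L, nrow(masks$gv), ncol(masks$gv))
  codes[masks$gv] <- 1L
  codes[masks$sdm] <- 2L
  png::writePNG(codes / 255, path)
  invisible(path)
}

#' Read a class-code mask PNG back into masks
#'
#' @param path a file written by [write_mask_png()].
#' @return A [class_masks()] object.
#' @export
read_mask_png <- function(path) {
  codes <- round(png::readPNG(path) * 255)
  class_masks(gv = codes == 1, sdm = codes == 2)
}
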