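# Image reading, cropping and per-band standardization/normalization.
#
# All classification downstream operates on the normalized representation:
# each band is z-scored over its own pixels (population sd) and then
# min-max rescaled so that the band spans exactly [0, 1023]. The two steps
# are kept separate and both exposed because threshold exploration is
# defined on the normalized scale.

#' Construct a raw quadrat image
#'
#' Wraps an H x W x 3 numeric array of 8-bit digital numbers (DN) in the
#' fixed band order red, green, blue.
#'
#' @param pixels numeric H x W x 3 array, values in \[0, 255\].
#' @param source_path optional path the image was read from.
#' @return A `quad_raw` object (the array, with attributes).
#' @export
raw_image <- function(pixels, source_path = NA_character_) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L) {
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  }
  d <- dim(pixels)
  if (d[3] != 3L) {
    stop("expected exactly 3 channels (R, G, B), got ", d[3], call. = FALSE)
  }
  if (d[1] < 1L || d[2] < 1L) stop("image must have at least one pixel", call. = FALSE)
  if (anyNA(pixels)) stop("image contains missing pixel values", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("digital numbers must lie in [0, 255]", call. = FALSE)
  }
  structure(pixels, class = "quad_raw", source_path = source_path)
}

#' Read an 8-bit RGB quadrat photograph
#'
#' Supports PNG, JPEG and TIFF. Images with an alpha channel or with other
#' than three channels are rejected.
#'
#' @param path path to a .png, .jpg/.jpeg, .tif/.tiff file.
#' @return A [raw_image()] with DN in \[0, 255\].
#' @export
read_quadrat <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' for ", path, call. = FALSE)
  )
  if (is.matrix(img)) {
    stop("grayscale image (1 channel) where RGB expected: ", path, call. = FALSE)
  }
  nc <- dim(img)[3]
  if (nc == 4L) stop("image has an alpha channel; flatten it first: ", path, call. = FALSE)
  if (nc != 3L) stop("expected 3 channels, got ", nc, ": ", path, call. = FALSE)
  # readers return [0, 1]; recover 8-bit DN
  raw_image(round(img * 255), source_path = path)
}

#' Crop rectangle
#'
#' 0-based top-left pixel offsets; the rectangle covers columns
#' `x0 .. x0 + width - 1` and rows `y0 .. y0 + height - 1` inclusive.
#'
#' @param x0,y0 non-negative integer offsets of the top-left corner.
#' @param width,height rectangle size in pixels, at least 1.
#' @return A `crop_rect` object.
#' @export
crop_rect <- function(x0, y0, width, height) {
  stopifnot(x0 >= 0, y0 >= 0, width >= 1, height >= 1)
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height)),
            class = "crop_rect")
}

crop_pixels <- function(pixels, crop) {
  d <- dim(pixels)
  if (crop$y0 + crop$height > d[1] || crop$x0 + crop$width > d[2]) {
    stop("crop rectangle exceeds image bounds (", d[1], " x ", d[2], ")",
         call. = FALSE)
  }
  rows <- seq.int(crop$y0 + 1L, crop$y0 + crop$height)
  cols <- seq.int(crop$x0 + 1L, crop$x0 + crop$width)
  pixels[rows, cols, , drop = FALSE]
}

#' Standardize one band (z-score)
#'
#' Subtracts the band mean and divides by the population standard
#' deviation (divide by N), both computed over all pixels of this one band
#' of this one image.
#'
#' @param band numeric matrix of pixel values.
#' @param label optional band name used in error messages.
#' @return Matrix of z-scores (mean 0, sd 1).
#' @export
standardize_band <- function(band, label = "band") {
  if (!is.matrix(band) || length(band) == 0L) {
    stop("`band` must be a non-empty matrix", call. = FALSE)
  }
  mu <- mean(band)
  s <- sqrt(mean((band - mu)^2))
  if (s == 0) {
    stop("degenerate ", label, ": all pixel values identical (sd = 0)",
         call. = FALSE)
  }
  (band - mu) / s
}

#' Min-max rescale a standardized band to \[0, 1023\]
#'
#' Maps the band minimum to 0 and the maximum to 1023 linearly, the 10-bit
#' range used by the classification thresholds. Values are kept as reals;
#' rounding happens only on export.
#'
#' @param std_band numeric matrix (typically a [standardize_band()] output).
#' @param label optional band name used in error messages.
#' @return Matrix with minimum exactly 0 and maximum exactly 1023.
#' @export
normalize_band <- function(std_band, label = "band") {
  lo <- min(std_band)
  hi <- max(std_band)
  if (hi == lo) {
    stop("degenerate ", label, ": max equals min, cannot rescale", call. = FALSE)
  }
  # dividing before scaling keeps the ratio in [0, 1] exactly, so the band
  # endpoints land on 0 and 1023 without floating-point spill
  ((std_band - lo) / (hi - lo)) * 1023
}

#' Construct a normalized image from three band matrices
#'
#' Mostly useful in tests and worked examples; [preprocess_image()] is the
#' standard route from a photograph.
#'
#' @param r,g,b numeric matrices of equal dimension with values in
#'   \[0, 1023\].
#' @param source optional identifier carried through to outputs.
#' @return A `quad_norm` object: a list of the three band matrices.
#' @export
normalized_image <- function(r, g, b, source = NA_character_) {
  bands <- list(r = r, g = g, b = b)
  dims <- lapply(bands, dim)
  if (!all(vapply(bands, is.matrix, logical(1))) ||
      !identical(dims$r, dims$g) || !identical(dims$r, dims$b)) {
    stop("r, g, b must be matrices of identical dimension", call. = FALSE)
  }
  rng <- range(unlist(lapply(bands, range)))
  if (rng[1] < 0 || rng[2] > 1023) {
    stop("normalized values must lie in [0, 1023]", call. = FALSE)
  }
  structure(bands, class = "quad_norm", source = source)
}

#' Preprocess a raw image into its normalized representation
#'
#' Optionally crops, then applies [standardize_band()] and
#' [normalize_band()] to each of the three bands independently. Band
#' statistics are computed after cropping, so the crop defines the scene.
#'
#' @param raw a [raw_image()] or plain H x W x 3 numeric array.
#' @param crop optional [crop_rect()].
#' @return A `quad_norm` object with bands `r`, `g`, `b` on \[0, 1023\].
#' @export
preprocess_image <- function(raw, crop = NULL) {
  if (!(is.array(raw) && length(dim(raw)) == 3L && dim(raw)[3] == 3L)) {
    stop("`raw` must be an H x W x 3 array", call. = FALSE)
  }
  px <- unclass(raw)
  if (!is.null(crop)) {
    stopifnot(inherits(crop, "crop_rect"))
    px <- crop_pixels(px, crop)
  }
  nm <- c("red", "green", "blue")
  src <- attr(raw, "source_path") %||% NA_character_
  bands <- lapply(1:3, function(i) {
    normalize_band(standardize_band(px[, , i], nm[i]), nm[i])
  })
  normalized_image(bands[[1]], bands[[2]], bands[[3]], source = src)
}

#' @export
print.quad_norm <- function(x, ...) {
  d <- dim(x$r)
  cat("<normalized quadrat image> ", d[1], " x ", d[2], " px\n", sep = "")
  for (b in c("r", "g", "b")) {
    cat(sprintf("  %s: min %.2f  mean %.2f  max %.2f\n",
                b, min(x[[b]]), mean(x[[b]]), max(x[[b]])))
  }
  invisible(x)
}

#' Export normalized bands as 16-bit grayscale TIFFs
#'
#' Values are rounded half away from zero to integers 0--1023 occupying the
#' low bits of the 16-bit range.
#'
#' @param norm a `quad_norm` image.
#' @param dir output directory (created if needed).
#' @param stem filename stem; files are `<stem>_r.tif` etc.
#' @return Invisibly, the three file paths.
#' @export
write_normalized_bands <- function(norm, dir, stem = "normalized") {
  stopifnot(inherits(norm, "quad_norm"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(3)
  for (i in seq_along(c("r", "g", "b"))) {
    b <- c("r", "g", "b")[i]
    v <- round_half_away(norm[[b]])
    paths[i] <- file.path(dir, paste0(stem, "_", b, ".tif"))
    tiff::writeTIFF(v / 65535, paths[i], bits.per.sample = 16L)
  }
  invisible(paths)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
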