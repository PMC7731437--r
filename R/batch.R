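# Batch processing: preprocess + classify a directory of quadrat images
# with optional per-image parameter overrides, and the cover-vs-index
# validation runner.

IMG_EXT <- c("png", "jpg", "jpeg", "tif", "tiff")

# the parameter ranges explored in practice; values outside draw a warning
G_RANGE <- c(30, 70)
D_RANGE <- c(0.5, 2)

check_param_ranges <- function(g1, g2, d, image = NULL) {
  tag <- if (is.null(image)) "" else paste0(" (", image, ")")
  if (g1 < G_RANGE[1] || g1 > G_RANGE[2] || g2 < G_RANGE[1] || g2 > G_RANGE[2]) {
    warning("g1/g2 outside the usually explored range [30, 70]", tag,
            call. = FALSE)
  }
  if (d < D_RANGE[1] || d > D_RANGE[2]) {
    warning("d outside the usually explored range [0.5, 2]", tag, call. = FALSE)
  }
}

read_overrides <- function(overrides) {
  if (is.null(overrides)) return(NULL)
  if (is.character(overrides)) {
    overrides <- utils::read.csv(overrides, stringsAsFactors = FALSE)
  }
  overrides <- as.data.frame(overrides)
  if (!"filename" %in% names(overrides)) {
    stop("overrides must have a `filename` column", call. = FALSE)
  }
  for (col in c("g1", "g2", "d")) {
    if (!col %in% names(overrides)) overrides[[col]] <- NA_real_
    overrides[[col]] <- suppressWarnings(as.numeric(overrides[[col]]))
  }
  overrides
}

params_for <- function(fname, defaults, overrides) {
  p <- defaults
  if (!is.null(overrides)) {
    row <- overrides[overrides$filename == fname, , drop = FALSE]
    if (nrow(row) == 1L) {
      if (!is.na(row$g1)) p$g1 <- row$g1
      if (!is.na(row$g2)) p$g2 <- row$g2
      if (!is.na(row$d)) p$d <- row$d
    }
  }
  classification_params(p$g1, p$g2, p$d)
}

#' Batch-classify a directory of quadrat images
#'
#' Every readable RGB image (png/jpg/jpeg/tif/tiff) in `input_dir` is
#' preprocessed and classified in lexicographic filename order; one CSV
#' row is written per successfully processed image. Unreadable or
#' degenerate images are logged, skipped and reported in the summary;
#' they never produce partial rows.
#'
#' @param input_dir directory of images.
#' @param output_csv path for the covers CSV (columns `image`,
#'   `total_pixels`, `gv_pixels`, `sdm_pixels`, `gv_cover_pct`,
#'   `sdm_cover_pct`, `g1`, `g2`, `d`; percentages fixed at 4 decimals so
#'   identical runs byte-reproduce the file).
#' @param masks_dir optional directory for per-image class-code mask PNGs.
#' @param defaults a [classification_params()] applied to every image.
#' @param overrides optional per-image overrides: CSV path or data frame
#'   with columns `filename`, `g1`, `g2`, `d`; blank cells inherit the
#'   defaults.
#' @param crop optional [crop_rect()] applied to all images.
#' @param quiet suppress the per-image log line.
#' @return Invisibly, a list: `covers` (tibble), `n_processed`,
#'   `n_failed`, `failures` (tibble of filename/error), `output_csv`,
#'   `masks_dir`.
#' @export
run_batch <- function(input_dir, output_csv, masks_dir = NULL,
                      defaults = classification_params(), overrides = NULL,
                      crop = NULL, quiet = FALSE) {
  if (!dir.exists(input_dir)) stop("input_dir does not exist: ", input_dir, call. = FALSE)
  files <- sort(list.files(input_dir,
                           pattern = paste0("\\.(", paste(IMG_EXT, collapse = "|"), ")$"),
                           ignore.case = TRUE))
  if (length(files) == 0L) stop("no images found in ", input_dir, call. = FALSE)
  overrides <- read_overrides(overrides)
  if (!is.null(overrides)) {
    missing <- setdiff(overrides$filename, files)
    if (length(missing)) {
      warning("override filenames not present in input_dir: ",
              paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(masks_dir) && !dir.exists(masks_dir)) {
    dir.create(masks_dir, recursive = TRUE)
  }

  rows <- list(); fails <- list()
  for (f in files) {
    p <- params_for(f, defaults, overrides)
    check_param_ranges(p$g1, p$g2, p$d, image = f)
    res <- tryCatch({
      norm <- preprocess_image(read_quadrat(file.path(input_dir, f)), crop)
      classify_image(norm, p)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[f]] <- conditionMessage(res)
      if (!quiet) message("FAIL  ", f, ": ", conditionMessage(res))
      next
    }
    cv <- res$cover
    rows[[f]] <- tibble::tibble(
      image = f, total_pixels = cv$total_pixels,
      gv_pixels = cv$gv_pixels, sdm_pixels = cv$sdm_pixels,
      gv_cover_pct = cv$gv_cover, sdm_cover_pct = cv$sdm_cover,
      g1 = p$g1, g2 = p$g2, d = p$d
    )
    if (!is.null(masks_dir)) {
      write_mask_png(res$masks,
                     file.path(masks_dir, paste0(tools::file_path_sans_ext(f), "_mask.png")))
    }
    if (!quiet) {
      message(sprintf("ok    %s  g1=%g g2=%g d=%g  GV %.2f%%  SDM %.2f%%",
                      f, p$g1, p$g2, p$d, cv$gv_cover, cv$sdm_cover))
    }
  }
  covers <- dplyr::bind_rows(rows)
  if (nrow(covers) > 0L) {
    out <- covers
    out$gv_cover_pct <- sprintf("%.4f", out$gv_cover_pct)
    out$sdm_cover_pct <- sprintf("%.4f", out$sdm_cover_pct)
    utils::write.csv(out, output_csv, row.names = FALSE, quote = FALSE)
  }
  invisible(list(
    covers = covers, n_processed = nrow(covers), n_failed = length(fails),
    failures = tibble::tibble(filename = names(fails),
                              error = unlist(unname(fails), use.names = FALSE) %||% character()),
    output_csv = output_csv, masks_dir = masks_dir
  ))
}

#' Validate batch covers against spectral indices
#'
#' Computes NDVI or CAI for every spectrum file in `spectra_dir`, joins on
#' the filename stem against the covers CSV, and regresses cover on the
#' index. For NDVI the response is the extracted GV cover; for CAI it is
#' NPV cover, the extracted SDM cover plus the observed litter cover
#' supplied in `litter_csv` (SDM alone is not expected to track CAI).
#'
#' @param cover_csv covers CSV written by [run_batch()].
#' @param spectra_dir directory of two-column spectrum files (.csv/.txt);
#'   stems must match the image stems.
#' @param index `"ndvi"` or `"cai"`.
#' @param litter_csv CSV with columns `image`, `litter_cover_pct`
#'   (required for `index = "cai"`).
#' @return List: `result` (a [validate_cover()] fit), `table`
#'   (per-quadrat tibble of stem, cover, index value).
#' @export
run_validation <- function(cover_csv, spectra_dir, index = c("ndvi", "cai"),
                           litter_csv = NULL) {
  index <- match.arg(index)
  covers <- utils::read.csv(cover_csv, stringsAsFactors = FALSE)
  covers$stem <- tools::file_path_sans_ext(covers$image)
  spec_files <- list.files(spectra_dir, pattern = "\\.(csv|txt)$", full.names = TRUE)
  if (length(spec_files) == 0L) stop("no spectrum files in ", spectra_dir, call. = FALSE)
  idx_fun <- if (index == "ndvi") ndvi else cai
  idx <- tibble::tibble(
    stem = tools::file_path_sans_ext(basename(spec_files)),
    index_value = vapply(spec_files, function(f) idx_fun(read_spectrum(f)), numeric(1))
  )
  if (index == "ndvi") {
    covers$response <- covers$gv_cover_pct
  } else {
    if (is.null(litter_csv)) {
      stop("CAI validation needs `litter_csv` (NPV = SDM + litter)", call. = FALSE)
    }
    litter <- utils::read.csv(litter_csv, stringsAsFactors = FALSE)
    litter$stem <- tools::file_path_sans_ext(litter$image)
    covers <- dplyr::inner_join(covers, litter[c("stem", "litter_cover_pct")], by = "stem")
    covers$response <- covers$sdm_cover_pct + covers$litter_cover_pct
  }
  tab <- dplyr::inner_join(
    tibble::tibble(stem = covers$stem, cover = covers$response), idx, by = "stem")
  if (nrow(tab) == 0L) {
    stop("no matching join keys between covers and spectra", call. = FALSE)
  }
  list(result = validate_cover(tab$cover, tab$index_value), table = tab)
}

#' Write a spectrum as a two-column CSV
#'
#' @param spec a [spectrum()].
#' @param path output path; the stem is the validation join key.
#' @return Invisibly, `path`.
#' @export
write_spectrum <- function(spec, path) {
  utils::write.csv(as.data.frame(spec)[c("wavelength_nm", "reflectance")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
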