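# Parameter-selection utilities: threshold statistics over reference GV
# pixels, and sensitivity sweeps of cover against d or the (g1, g2) pair.

#' Explore GV thresholds over a reference region
#'
#' Computes min/max/mean/sd of the normalized green-minus-red and
#' green-minus-blue differences over a user-supplied mask of pixels known
#' to be green vegetation. The minima are the candidate `g1` and `g2`: any
#' threshold at or below the minimum keeps every reference pixel in the
#' GV class.
#'
#' @param norm a `quad_norm` image.
#' @param reference_mask logical matrix marking known-GV pixels (hand
#'   drawn, or a synthetic scene's ground-truth labels).
#' @return Tibble with one row per difference (`green_red`, `green_blue`)
#'   and columns `min`, `max`, `mean`, `sd`, `n_pixels`. `sd` is the
#'   sample standard deviation (0 for a single pixel).
#' @export
explore_gv_thresholds <- function(norm, reference_mask) {
  stopifnot(inherits(norm, "quad_norm"))
  if (!identical(dim(reference_mask), dim(norm$r))) {
    stop("`reference_mask` shape does not match the image", call. = FALSE)
  }
  if (!any(reference_mask)) stop("reference mask is empty", call. = FALSE)
  diffs <- list(
    green_red  = (norm$g - norm$r)[reference_mask],
    green_blue = (norm$g - norm$b)[reference_mask]
  )
  purrr::imap_dfr(diffs, function(v, nm) {
    tibble::tibble(
      difference = nm, min = min(v), max = max(v), mean = mean(v),
      sd = if (length(v) > 1L) stats::sd(v) else 0,
      n_pixels = length(v)
    )
  })
}

#' SDM-cover sensitivity to the brightness multiplier d
#'
#' Runs [classify_image()] at each `d` with fixed `g1`, `g2`.
#'
#' @param norm a `quad_norm` image.
#' @param g1,g2 GV thresholds held fixed.
#' @param d_values strictly positive multipliers, in the order to report.
#' @return A `quad_sweep` tibble with columns `d` and `sdm_cover`.
#' @export
sweep_d <- function(norm, g1 = 60, g2 = 60, d_values = c(0.5, 0.7, 1, 1.5, 2)) {
  if (length(d_values) == 0L) stop("`d_values` must be non-empty", call. = FALSE)
  if (any(d_values <= 0)) stop("all `d_values` must be positive", call. = FALSE)
  out <- purrr::map_dfr(d_values, function(d) {
    res <- classify_image(norm, classification_params(g1 = g1, g2 = g2, d = d))
    tibble::tibble(d = d, sdm_cover = res$cover$sdm_cover)
  })
  structure(out, class = c("quad_sweep", class(out)), parameter = "d",
            response = "sdm_cover")
}

#' GV-cover sensitivity to the (g1, g2) threshold pair
#'
#' @param norm a `quad_norm` image.
#' @param g_pairs data frame with columns `g1` and `g2`, one row per pair.
#' @param d SDM multiplier held fixed (reported for completeness; it does
#'   not affect GV cover).
#' @return A `quad_sweep` tibble with columns `g1`, `g2`, `gv_cover`.
#' @export
sweep_g <- function(norm, g_pairs, d = 1) {
  g_pairs <- as.data.frame(g_pairs)
  if (nrow(g_pairs) == 0L || !all(c("g1", "g2") %in% names(g_pairs))) {
    stop("`g_pairs` must have columns g1, g2 and at least one row", call. = FALSE)
  }
  out <- purrr::pmap_dfr(g_pairs[c("g1", "g2")], function(g1, g2) {
    res <- classify_image(norm, classification_params(g1 = g1, g2 = g2, d = d))
    tibble::tibble(g1 = g1, g2 = g2, gv_cover = res$cover$gv_cover)
  })
  structure(out, class = c("quad_sweep", class(out)), parameter = "g1,g2",
            response = "gv_cover")
}

#' @method autoplot quad_sweep
#' @param object a `quad_sweep` tibble.
#' @param ... unused.
#' @export
autoplot.quad_sweep <- function(object, ...) {
  resp <- attr(object, "response")
  xvar <- if (attr(object, "parameter") == "d") "d" else "g1"
  ggplot2::ggplot(object, ggplot2::aes(.data[[xvar]], .data[[resp]])) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = attr(object, "parameter"),
      y = paste0(sub("_cover", "", resp), " cover (%)"),
      title = "Cover sensitivity"
    ) +
    ggplot2::theme_minimal()
}
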