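# Spectral indices from field reflectance spectra and linear-regression
# validation of image-extracted covers.
#
# NDVI = (rho800 - rho670) / (rho800 + rho670) tracks green biomass; CAI =
# 100 * (0.5 * (rho2030 + rho2210) - rho2100) tracks dry plant material
# through the 2100 nm cellulose-lignin absorption feature. Reflectance at
# a named wavelength is obtained by linear interpolation between the
# bracketing samples (exact when the instrument resamples to 1 nm).

#' Construct a reflectance spectrum
#'
#' @param wavelength_nm strictly increasing wavelengths in nanometres,
#'   within \[350, 2500\].
#' @param reflectance reflectance factors in \[0, 1\], same length.
#' @return A `spectrum` tibble with columns `wavelength_nm`, `reflectance`.
#' @export
spectrum <- function(wavelength_nm, reflectance) {
  if (length(wavelength_nm) != length(reflectance)) {
    stop("wavelength and reflectance lengths differ", call. = FALSE)
  }
  if (any(diff(wavelength_nm) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (min(wavelength_nm) < 350 || max(wavelength_nm) > 2500) {
    stop("wavelengths must lie within [350, 2500] nm", call. = FALSE)
  }
  if (min(reflectance) < 0 || max(reflectance) > 1) {
    stop("reflectance must lie within [0, 1]", call. = FALSE)
  }
  out <- tibble::tibble(wavelength_nm = as.numeric(wavelength_nm),
                        reflectance = as.numeric(reflectance))
  class(out) <- c("spectrum", class(out))
  out
}

#' Read a two-column wavelength/reflectance file
#'
#' Plain text or CSV, two columns (wavelength in nm, reflectance), header
#' optional. The filename stem is the join key against cover tables.
#'
#' @param path file path.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("no such spectrum file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, "[,\t ]+")[[1]][1])
  ))
  sep <- if (grepl(",", first)) "," else ""
  df <- if (has_header) {
    utils::read.table(path, header = TRUE, sep = sep)
  } else {
    utils::read.table(path, header = FALSE, sep = sep,
                      col.names = c("wavelength_nm", "reflectance"))
  }
  spectrum(df[[1]], df[[2]])
}

#' Reflectance at a wavelength, linearly interpolated
#'
#' @param spec a [spectrum()].
#' @param wl wavelength(s) in nm; must be covered by the spectrum.
#' @return Numeric reflectance value(s).
#' @export
reflectance_at <- function(spec, wl) {
  rng <- range(spec$wavelength_nm)
  if (any(wl < rng[1] | wl > rng[2])) {
    stop("wavelength ", paste(wl[wl < rng[1] | wl > rng[2]], collapse = ", "),
         " nm outside spectrum range [", rng[1], ", ", rng[2], "]", call. = FALSE)
  }
  stats::approx(spec$wavelength_nm, spec$reflectance, xout = wl)$y
}

#' Normalized difference vegetation index
#'
#' `(rho800 - rho670) / (rho800 + rho670)`.
#'
#' @param spec a [spectrum()] covering 670 and 800 nm.
#' @return NDVI in \[-1, 1\].
#' @export
ndvi <- function(spec) {
  r <- reflectance_at(spec, c(670, 800))
  if (r[1] + r[2] == 0) stop("rho670 + rho800 is zero; NDVI undefined", call. = FALSE)
  (r[2] - r[1]) / (r[2] + r[1])
}

#' Cellulose absorption index
#'
#' `100 * (0.5 * (rho2030 + rho2210) - rho2100)`: the depth of the
#' 2100 nm absorption feature below its shoulders, in percent reflectance.
#'
#' @param spec a [spectrum()] covering 2030, 2100 and 2210 nm.
#' @return CAI (index units; positive over dry plant material).
#' @export
cai <- function(spec) {
  r <- reflectance_at(spec, c(2030, 2100, 2210))
  100 * (0.5 * (r[1] + r[3]) - r[2])
}

#' Regress extracted cover on a spectral index
#'
#' Ordinary least squares of cover (%) on the index, the validation design
#' used for GV cover against NDVI and NPV cover (SDM + litter) against
#' CAI. The p-value is the two-sided t-test on the slope with n - 2
#' degrees of freedom.
#'
#' @param covers numeric cover percentages (response).
#' @param indices numeric index values (predictor), same length.
#' @return A `cover_validation` object with `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n` and the underlying `lm` fit.
#' @export
validate_cover <- function(covers, indices) {
  if (length(covers) != length(indices)) stop("length mismatch", call. = FALSE)
  n <- length(covers)
  if (n < 3L) stop("need at least 3 paired observations, got ", n, call. = FALSE)
  if (stats::var(indices) == 0) {
    stop("degenerate predictor: index values are all equal", call. = FALSE)
  }
  fit <- stats::lm(cover ~ index,
                   data = data.frame(cover = covers, index = indices))
  # exact linear inputs are legitimate here; silence the perfect-fit note
  sm <- suppressWarnings(summary(fit))
  if (stats::var(covers) == 0) {
    # constant response: zero slope explains nothing, by convention R^2 = 0
    r2 <- 0
    p <- 1
  } else {
    r2 <- sm$r.squared
    p <- unname(sm$coefficients[2, 4])
  }
  structure(
    list(
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      r_squared = r2, p_value = p,
      n = n, fit = fit
    ),
    class = "cover_validation"
  )
}

#' @export
print.cover_validation <- function(x, ...) {
  cat("<cover ~ index validation>\n")
  cat(sprintf("  cover = %.4f + %.4f * index   (n = %d)\n",
              x$intercept, x$slope, x$n))
  cat(sprintf("  R^2 = %.3f   p = %.3g\n", x$r_squared, x$p_value))
  invisible(x)
}

#' @rdname validate_cover
#' @param x a `cover_validation`.
#' @param ... unused.
#' @method tidy cover_validation
#' @export
tidy.cover_validation <- function(x, ...) {
  sm <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = c("(Intercept)", "index"),
    estimate = unname(sm[, 1]), std.error = unname(sm[, 2]),
    statistic = unname(sm[, 3]), p.value = unname(sm[, 4])
  )
}

#' @rdname validate_cover
#' @method glance cover_validation
#' @export
glance.cover_validation <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, p.value = x$p_value,
                 slope = x$slope, intercept = x$intercept, n = x$n)
}

#' @method autoplot cover_validation
#' @param object a `cover_validation`.
#' @export
autoplot.cover_validation <- function(object, ...) {
  df <- object$fit$model
  ggplot2::ggplot(df, ggplot2::aes(.data$index, .data$cover)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         color = "darkgreen") +
    ggplot2::labs(
      x = "spectral index", y = "extracted cover (%)",
      title = sprintf("R² = %.3f, p = %.3g, n = %d",
                      object$r_squared, object$p_value, object$n)
    ) +
    ggplot2::theme_minimal()
}
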