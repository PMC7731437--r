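# Independent per-pixel scalar-loop reference implementations. These are
# deliberately written as naive loops over pixels, sharing no code with
# the vectorized package path.

oracle_preprocess <- function(px, crop = NULL) {
  px <- unclass(px)
  if (!is.null(crop)) {
    px <- px[(crop$y0 + 1):(crop$y0 + crop$height),
             (crop$x0 + 1):(crop$x0 + crop$width), , drop = FALSE]
  }
  H <- dim(px)[1]; W <- dim(px)[2]
  out <- vector("list", 3)
  for (ch in 1:3) {
    b <- px[, , ch]
    s <- 0
    for (i in 1:H) for (j in 1:W) s <- s + b[i, j]
    m <- s / (H * W)
    ss <- 0
    for (i in 1:H) for (j in 1:W) ss <- ss + (b[i, j] - m)^2
    sdev <- sqrt(ss / (H * W))
    z <- matrix(0, H, W)
    for (i in 1:H) for (j in 1:W) z[i, j] <- (b[i, j] - m) / sdev
    lo <- z[1, 1]; hi <- z[1, 1]
    for (i in 1:H) for (j in 1:W) {
      if (z[i, j] < lo) lo <- z[i, j]
      if (z[i, j] > hi) hi <- z[i, j]
    }
    nb <- matrix(0, H, W)
    for (i in 1:H) for (j in 1:W) nb[i, j] <- ((z[i, j] - lo) / (hi - lo)) * 1023
    out[[ch]] <- nb
  }
  names(out) <- c("r", "g", "b")
  out
}

oracle_classify <- function(bands, g1 = 60, g2 = 60, d = 1) {
  H <- nrow(bands$r); W <- ncol(bands$r)
  mr <- 0; mg <- 0; mb <- 0
  for (i in 1:H) for (j in 1:W) {
    mr <- mr + bands$r[i, j]; mg <- mg + bands$g[i, j]; mb <- mb + bands$b[i, j]
  }
  mr <- mr / (H * W); mg <- mg / (H * W); mb <- mb / (H * W)
  gv <- matrix(FALSE, H, W); sdm <- matrix(FALSE, H, W)
  for (i in 1:H) for (j in 1:W) {
    r <- bands$r[i, j]; g <- bands$g[i, j]; b <- bands$b[i, j]
    if (g - r > g1 && g - b > g2) {
      gv[i, j] <- TRUE
    } else if (r > d * mr && g > d * mg && b > d * mb) {
      sdm[i, j] <- TRUE
    }
  }
  list(gv = gv, sdm = sdm, mean_r = mr, mean_g = mg, mean_b = mb)
}

# closed-form simple linear regression via normal equations, with the
# slope t-test assembled from scratch
oracle_ols <- function(y, x) {
  n <- length(y)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  sse <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  se_slope <- sqrt(sse / (n - 2) / sxx)
  tval <- slope / se_slope
  list(slope = slope, intercept = intercept,
       r_squared = 1 - sse / sst,
       p_value = 2 * stats::pt(-abs(tval), df = n - 2))
}
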