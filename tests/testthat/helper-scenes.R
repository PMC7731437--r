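# shared fixture builders

# random 8-bit raw image as an H x W x 3 integer array
random_raw <- function(h, w, seed) {
  withr::with_seed(seed, {
    raw_image(array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3)))
  })
}

# normalized image with bands drawn uniformly on [0, 1023]
random_norm <- function(h, w, seed) {
  withr::with_seed(seed, {
    m <- function() matrix(runif(h * w, 0, 1023), h, w)
    normalized_image(m(), m(), m())
  })
}

# the four-pixel worked image: p1 GV-colored, p2 uniformly bright,
# p3 = p4 dark
worked_example_norm <- function() {
  normalized_image(
    r = matrix(c(300, 100, 800, 100), 2, 2),
    g = matrix(c(500, 100, 800, 100), 2, 2),
    b = matrix(c(200, 100, 800, 100), 2, 2)
  )
}

# replicate every pixel of an H x W x 3 array into an s x s block
block_replicate <- function(px, s) {
  px <- unclass(px)
  d <- dim(px)
  out <- array(0, c(d[1] * s, d[2] * s, 3))
  for (ch in 1:3) {
    out[, , ch] <- px[rep(seq_len(d[1]), each = s), rep(seq_len(d[2]), each = s), ch]
  }
  out
}

# fractions drawn uniformly on (0, 0.6) per component, renormalized
random_fractions <- function(seed) {
  withr::with_seed(seed, {
    u <- runif(5, 0, 0.6)
    stats::setNames(u / sum(u), c("gv", "sdm", "litter", "crust", "soil"))
  })
}
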