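test_that("pixel allocation is exact under largest-remainder apportionment", {
  q <- generate_quadrat(scene_spec(100, 100, c(gv = 0.3, sdm = 0.2, soil = 0.5),
                                   seed = 7))
  expect_equal(q$true_fractions[["gv"]], 0.30)
  expect_equal(q$true_fractions[["sdm"]], 0.20)
  expect_equal(q$true_fractions[["soil"]], 0.50)
  # labels cover every pixel and realized fractions match the label counts
  expect_false(any(is.na(q$labels)))
  expect_equal(sum(q$true_fractions), 1)
  expect_equal(unname(table(q$labels)["soil"]), 5000L)

  # fractions that don't tile evenly still sum to the full image
  q2 <- generate_quadrat(scene_spec(13, 17, c(gv = 1 / 3, sdm = 1 / 3, soil = 1 / 3),
                                    seed = 2))
  expect_equal(sum(table(q2$labels)), 13L * 17L)
})

test_that("invalid scene specifications are rejected", {
  expect_error(scene_spec(50, 50, c(gv = 0.4, sdm = 0.5)), "sum to 1")
  expect_error(scene_spec(50, 50, c(weeds = 1)), "must be named over")
  expect_error(scene_spec(50, 50, c(gv = -0.1, sdm = 1.1)), "non-negative")
  expect_error(
    generate_quadrat(scene_spec(2, 2, c(gv = 0.96, sdm = 0.01, litter = 0.01,
                                        crust = 0.01, soil = 0.01), seed = 1)),
    "too small")
})

test_that("scene generation is deterministic in the seed", {
  sp <- scene_spec(40, 40, c(gv = 0.3, sdm = 0.3, litter = 0.2, crust = 0.1,
                             soil = 0.1), seed = 5)
  a <- generate_quadrat(sp)
  b <- generate_quadrat(sp)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(a$labels, b$labels)

  other <- generate_quadrat(scene_spec(40, 40, sp$fractions, seed = 6))
  expect_false(identical(a$labels, other$labels))
})

test_that("default thresholds recover noise-free scenes exactly", {
  for (seed in c(7, 19)) {
    fr <- c(gv = 0.25, sdm = 0.25, litter = 0.2, crust = 0.15, soil = 0.15)
    q <- generate_quadrat(scene_spec(60, 60, fr, noise_sd = 0, seed = seed))
    res <- classify_image(preprocess_image(q$image))
    expect_equal(res$cover$gv_cover, 100 * q$true_fractions[["gv"]])
    expect_equal(res$cover$sdm_cover, 100 * q$true_fractions[["sdm"]])
  }
})

test_that("patch arrangement preserves counts and exercises cropping", {
  sp <- scene_spec(30, 30, c(gv = 0.5, sdm = 0.5), arrangement = "patch", seed = 1)
  q <- generate_quadrat(sp)
  expect_equal(q$true_fractions[["gv"]], 0.5)
  # patches are contiguous in row-major order: first rows all gv
  expect_true(all(q$labels[1:10, ] == "gv"))
})

test_that("scenes round-trip to disk with label codes and a JSON sidecar", {
  tmp <- withr::local_tempdir()
  q <- generate_quadrat(scene_spec(20, 20, c(gv = 0.4, sdm = 0.3, soil = 0.3),
                                   seed = 9))
  paths <- write_scene(q, tmp, stem = "s1")
  img <- read_quadrat(paths[["image"]])
  expect_equal(unclass(img), unclass(q$image), ignore_attr = TRUE)
  codes <- round(png::readPNG(paths[["labels"]]) * 255)
  expect_identical(matrix(c("gv", "sdm", "litter", "crust", "soil")[codes + 1],
                          20, 20), q$labels)
  side <- jsonlite::read_json(paths[["sidecar"]])
  expect_equal(side$true_fractions$gv, 0.4)
  expect_equal(side$seed, 9)
})

test_that("pure endmember spectra reproduce their index values", {
  gv_only <- generate_spectrum(1, 0, 0, noise_sd = 0)
  expect_equal(ndvi(gv_only), (0.5 - 0.05) / (0.5 + 0.05), tolerance = 1e-12)
  expect_equal(cai(gv_only), 0, tolerance = 1e-12)

  npv_only <- generate_spectrum(0, 1, 0, noise_sd = 0)
  expect_equal(cai(npv_only), 5, tolerance = 1e-12)

  no_npv <- generate_spectrum(0.6, 0, 0.4, noise_sd = 0)
  expect_equal(cai(no_npv), 0, tolerance = 1e-12)

  expect_error(generate_spectrum(0.5, 0.3, 0.1), "sum to 1")
})

test_that("NDVI rises with green fraction and CAI with dry-matter fraction", {
  grid <- seq(0, 1, by = 0.1)
  ndvi_vals <- vapply(grid, function(f)
    ndvi(generate_spectrum(f, 0, 1 - f, noise_sd = 0)), numeric(1))
  expect_true(all(diff(ndvi_vals) > 0))

  cai_vals <- vapply(grid, function(f)
    cai(generate_spectrum(0, f, 1 - f, noise_sd = 0)), numeric(1))
  expect_true(all(diff(cai_vals) > 0))
})

test_that("spectral noise is seeded and bounded", {
  a <- generate_spectrum(0.5, 0.3, 0.2, seed = 4)
  b <- generate_spectrum(0.5, 0.3, 0.2, seed = 4)
  expect_identical(a$reflectance, b$reflectance)
  clean <- generate_spectrum(0.5, 0.3, 0.2, noise_sd = 0)
  expect_lt(max(abs(a$reflectance - clean$reflectance)), 0.002 * 5)
})

test_that("noisy scenes stay close to ground truth at default conditions", {
  hits_gv <- 0; hits_sdm <- 0; n <- 20
  for (i in seq_len(n)) {
    fr <- random_fractions(300 + i)
    q <- generate_quadrat(scene_spec(80, 80, fr, seed = 300 + i))
    res <- classify_image(preprocess_image(q$image))
    if (abs(res$cover$gv_cover - 100 * q$true_fractions[["gv"]]) <= 2) {
      hits_gv <- hits_gv + 1
    }
    if (abs(res$cover$sdm_cover - 100 * q$true_fractions[["sdm"]]) <= 5) {
      hits_sdm <- hits_sdm + 1
    }
  }
  expect_gte(hits_gv / n, 0.9)
  expect_gte(hits_sdm / n, 0.9)
})
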