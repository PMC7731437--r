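write_test_scenes <- function(dir, n = 3, seed = 60, noise_sd = 8) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  quads <- lapply(seq_len(n), function(i) {
    fr <- random_fractions(seed + i)
    generate_quadrat(scene_spec(40, 40, fr, noise_sd = noise_sd, seed = seed + i))
  })
  for (i in seq_len(n)) {
    png::writePNG(unclass(quads[[i]]$image) / 255,
                  file.path(dir, sprintf("quad%02d.png", i)))
  }
  quads
}

test_that("a batch run produces one CSV row per image, matching single runs", {
  tmp <- withr::local_tempdir()
  input <- file.path(tmp, "imgs")
  quads <- write_test_scenes(input, n = 3)
  out_csv <- file.path(tmp, "covers.csv")
  masks <- file.path(tmp, "masks")
  summary <- run_batch(input, out_csv, masks_dir = masks, quiet = TRUE)

  expect_equal(summary$n_processed, 3L)
  expect_equal(summary$n_failed, 0L)
  got <- utils::read.csv(out_csv)
  expect_equal(nrow(got), 3L)
  expect_equal(got$image, sprintf("quad%02d.png", 1:3))

  single <- classify_image(preprocess_image(quads[[2]]$image))
  expect_equal(got$gv_cover_pct[2], round(single$cover$gv_cover, 4))
  expect_equal(got$sdm_cover_pct[2], round(single$cover$sdm_cover, 4))
  expect_true(file.exists(file.path(masks, "quad02_mask.png")))
})

test_that("per-image overrides replace only the fields they specify", {
  tmp <- withr::local_tempdir()
  input <- file.path(tmp, "imgs")
  write_test_scenes(input, n = 2)
  ov <- file.path(tmp, "overrides.csv")
  writeLines(c("filename,g1,g2,d", "quad01.png,,,1.5"), ov)
  out_default <- file.path(tmp, "default.csv")
  out_over <- file.path(tmp, "override.csv")
  run_batch(input, out_default, quiet = TRUE)
  run_batch(input, out_over, overrides = ov, quiet = TRUE)

  def <- utils::read.csv(out_default)
  ovr <- utils::read.csv(out_over)
  expect_equal(ovr$d, c(1.5, 1))
  expect_equal(ovr$g1, c(60, 60))  # blank cells inherit defaults
  expect_lte(ovr$sdm_cover_pct[1], def$sdm_cover_pct[1])  # higher d never adds SDM
  expect_equal(ovr$gv_cover_pct, def$gv_cover_pct)
})

test_that("a corrupt file is skipped, reported, and leaves other rows intact", {
  tmp <- withr::local_tempdir()
  input <- file.path(tmp, "imgs")
  write_test_scenes(input, n = 2)
  writeLines("this is not a png", file.path(input, "broken.png"))
  out_csv <- file.path(tmp, "covers.csv")
  summary <- run_batch(input, out_csv, quiet = TRUE)
  expect_equal(summary$n_failed, 1L)
  expect_equal(summary$failures$filename, "broken.png")
  expect_equal(summary$n_processed, 2L)
  expect_equal(nrow(utils::read.csv(out_csv)), 2L)
})

test_that("identical configurations byte-reproduce the covers CSV", {
  tmp <- withr::local_tempdir()
  input <- file.path(tmp, "imgs")
  write_test_scenes(input, n = 2)
  a <- file.path(tmp, "a.csv"); b <- file.path(tmp, "b.csv")
  run_batch(input, a, quiet = TRUE)
  run_batch(input, b, quiet = TRUE)
  expect_identical(readLines(a), readLines(b))
})

test_that("parameters outside the usual ranges warn but still run", {
  tmp <- withr::local_tempdir()
  input <- file.path(tmp, "imgs")
  write_test_scenes(input, n = 1)
  out_csv <- file.path(tmp, "covers.csv")
  expect_warning(
    run_batch(input, out_csv, defaults = classification_params(d = 3), quiet = TRUE),
    "\\[0.5, 2\\]")
  expect_equal(nrow(utils::read.csv(out_csv)), 1L)
})

test_that("batch covers validate against paired synthetic spectra", {
  tmp <- withr::local_tempdir()
  input <- file.path(tmp, "imgs"); spdir <- file.path(tmp, "spectra")
  dir.create(input); dir.create(spdir)
  pairs <- generate_paired_set(n = 12, width = 50, height = 50, seed = 400,
                               spectral_noise_sd = 0)
  litter <- data.frame(image = character(), litter_cover_pct = numeric())
  for (i in seq_along(pairs)) {
    stem <- sprintf("q%02d", i)
    png::writePNG(unclass(pairs[[i]]$quadrat$image) / 255,
                  file.path(input, paste0(stem, ".png")))
    write_spectrum(pairs[[i]]$spectrum, file.path(spdir, paste0(stem, ".csv")))
    litter <- rbind(litter, data.frame(
      image = paste0(stem, ".png"),
      litter_cover_pct = 100 * pairs[[i]]$quadrat$true_fractions[["litter"]]))
  }
  litter_csv <- file.path(tmp, "litter.csv")
  utils::write.csv(litter, litter_csv, row.names = FALSE)
  out_csv <- file.path(tmp, "covers.csv")
  run_batch(input, out_csv, quiet = TRUE)

  val_gv <- run_validation(out_csv, spdir, index = "ndvi")
  expect_equal(val_gv$result$n, 12L)
  expect_gte(val_gv$result$r_squared, 0.9)

  val_npv <- run_validation(out_csv, spdir, index = "cai", litter_csv = litter_csv)
  expect_gte(val_npv$result$r_squared, 0.9)
  expect_error(run_validation(out_csv, spdir, index = "cai"), "litter_csv")
})

test_that("validation demands matching keys and enough pairs", {
  tmp <- withr::local_tempdir()
  input <- file.path(tmp, "imgs"); spdir <- file.path(tmp, "spectra")
  write_test_scenes(input, n = 2)
  dir.create(spdir)
  out_csv <- file.path(tmp, "covers.csv")
  run_batch(input, out_csv, quiet = TRUE)

  write_spectrum(generate_spectrum(0.5, 0.3, 0.2, noise_sd = 0),
                 file.path(spdir, "unrelated.csv"))
  expect_error(run_validation(out_csv, spdir, index = "ndvi"), "no matching")

  write_spectrum(generate_spectrum(0.5, 0.3, 0.2, noise_sd = 0),
                 file.path(spdir, "quad01.csv"))
  expect_error(run_validation(out_csv, spdir, index = "ndvi"), "at least 3")
})

test_that("empty or missing input directories fail loudly", {
  tmp <- withr::local_tempdir()
  empty <- file.path(tmp, "empty"); dir.create(empty)
  expect_error(run_batch(empty, file.path(tmp, "o.csv")), "no images")
  expect_error(run_batch(file.path(tmp, "nope"), file.path(tmp, "o.csv")),
               "does not exist")
})
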