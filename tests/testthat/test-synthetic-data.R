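# Synthetic histology generator: tiles, pseudo-WSIs, cohorts.

test_that("tile generator honours degenerate parameters and determinism", {
  flat <- texture_class_params(nucleus_density = 0, speckle_sd = 0)
  img <- generate_tile_image(flat, seed = 3, size = 64)
  expect_equal(dim(img), c(64, 64, 3))
  for (ch in 1:3) {
    expect_length(unique(as.vector(img[, , ch])), 1)
  }

  p <- texture_class_params()
  a <- generate_tile_image(p, seed = 11, size = 96)
  b <- generate_tile_image(p, seed = 11, size = 96)
  expect_identical(a, b)
  expect_false(identical(a, generate_tile_image(p, seed = 12, size = 96)))
  expect_true(min(a) >= 0 && max(a) <= 255)
})

test_that("invalid texture parameters are rejected", {
  expect_error(texture_class_params(nucleus_intensity = 300), "intensities")
  expect_error(texture_class_params(nucleus_density = -1), "nucleus_density")
  expect_error(texture_class_params(nucleus_radius_mean = 0), "radius_mean")
})

test_that("nucleus counts follow the configured Poisson density", {
  lambda <- 30
  p <- texture_class_params(nucleus_density = lambda / 64^2, speckle_sd = 0)
  counts <- vapply(1:200, function(s) {
    attr(generate_tile_image(p, seed = s, size = 64), "n_nuclei")
  }, numeric(1))
  se <- sqrt(lambda / length(counts))
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("pseudo-WSI textures the polygon interior and blanks the rest", {
  p <- texture_class_params(speckle_sd = 0)
  full <- matrix(c(0, 0, 128, 0, 128, 96, 0, 96), ncol = 2, byrow = TRUE)
  w <- generate_pseudo_wsi(128, 96, full, p, seed = 1)
  lum <- to_grayscale(w$image)
  expect_true(all(lum <= 220)) # textured everywhere, no blank pixels

  half <- matrix(c(0, 0, 64, 0, 64, 96, 0, 96), ncol = 2, byrow = TRUE)
  w2 <- generate_pseudo_wsi(128, 96, half, p, seed = 1)
  frac <- mean(to_grayscale(w2$image) <= 220)
  expect_lt(abs(frac - 0.5), 0.02)
  expect_s3_class(w2$annotation, "roi_annotation")

  expect_error(generate_pseudo_wsi(128, 96, matrix(c(0, 0, 5, 5), 2, 2), p, 1),
               "3 distinct vertices")
  degenerate <- matrix(c(0, 0, 10, 0, 20, 0), ncol = 2, byrow = TRUE)
  expect_error(generate_pseudo_wsi(128, 96, degenerate, p, 1), "empty interior")
  outside <- matrix(c(-5, 0, 50, 0, 50, 50), ncol = 2, byrow = TRUE)
  expect_error(generate_pseudo_wsi(128, 96, outside, p, 1), "bounds")
})

test_that("cohort generation matches configuration and is reproducible", {
  cfg <- cohort_config(n_patients = 200, tiles_per_patient_min = 2,
                       tiles_per_patient_max = 5, seed = 9)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$patients), 200)
  # prevalence within binomial noise of 59/120
  prev <- mean(co$patients$label == "PR")
  p0 <- 59 / 120
  expect_lt(abs(prev - p0), 3 * sqrt(p0 * (1 - p0) / 200))
  expect_true(all(co$patients$n_tiles >= 2 & co$patients$n_tiles <= 5))
  expect_true(all(co$patients$gender %in% c("male", "female")))
  expect_true(all(co$patients$t_stage %in% c("T2", "T3", "T4")))
  expect_true(all(co$patients$n_stage %in% c("N0", "N1", "N2")))
  expect_true(all(co$patients$cea %in% c("normal", "abnormal")))
  expect_false(any(duplicated(co$tiles$seed)))
  expect_equal(nrow(co$tiles), sum(co$patients$n_tiles))

  co2 <- generate_cohort(cfg)
  expect_identical(co$patients, co2$patients)
  expect_identical(co$tiles, co2$tiles)

  expect_error(cohort_config(pr_prevalence = 1.2), "pr_prevalence")
  expect_error(cohort_config(n_patients = 1), "n_patients")
})

test_that("cohort tiles regenerate deterministically and differ by class", {
  cfg <- cohort_config(n_patients = 6, tiles_per_patient_min = 2,
                       tiles_per_patient_max = 2, tile_size = 64, seed = 21)
  co <- generate_cohort(cfg)
  tid <- co$tiles$tile_id[1]
  expect_identical(cohort_tile_image(co, tid), cohort_tile_image(co, tid))
  expect_error(cohort_tile_image(co, "nope"), "unknown tile_id")
  # distinct tiles get distinct images
  expect_false(identical(cohort_tile_image(co, co$tiles$tile_id[1]),
                         cohort_tile_image(co, co$tiles$tile_id[2])))
})

test_that("effect size controls second-order texture separation monotonically", {
  sep <- vapply(c(0, 0.5, 1), function(es) {
    cp <- class_params_for_effect(es)
    f_non <- vapply(1:6, function(s) {
      extract_features(generate_tile_image(cp$nonpr, s, 128))[["contrast_d1_a0"]]
    }, numeric(1))
    f_pr <- vapply(7:12, function(s) {
      extract_features(generate_tile_image(cp$pr, s, 128))[["contrast_d1_a0"]]
    }, numeric(1))
    mean(f_pr) - mean(f_non)
  }, numeric(1))
  expect_lt(abs(sep[1]), abs(sep[2]))
  expect_lt(sep[2], sep[3])
  # at effect 0 the two classes share one distribution by construction
  cp0 <- class_params_for_effect(0)
  expect_identical(cp0$nonpr, cp0$pr)
})

test_that("cohort and ROI artifacts round-trip through disk formats", {
  cfg <- cohort_config(n_patients = 4, tiles_per_patient_min = 1,
                       tiles_per_patient_max = 2, tile_size = 48, seed = 2)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir, images = TRUE)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  tab <- read.csv(file.path(dir, "cohort.csv"), stringsAsFactors = FALSE)
  expect_equal(tab$patient_id, co$patients$patient_id)
  tid <- co$tiles$tile_id[1]
  img <- read_image_png(file.path(dir, paste0(tid, ".png")))
  # PNG is 8-bit; round-trip within quantization error
  expect_lt(max(abs(img - cohort_tile_image(co, tid))), 0.51)

  ann <- roi_annotation(matrix(c(1, 2, 40, 3, 20, 30), ncol = 2, byrow = TRUE))
  f <- file.path(dir, "roi.geojson")
  write_roi_geojson(ann, f)
  ann2 <- read_roi_geojson(f)
  expect_equal(ann2$polygons[[1]], ann$polygons[[1]])
  expect_equal(ann2$magnification, "x400")
})
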