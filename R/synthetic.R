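# Synthetic histology: nuclei-textured tiles, pseudo-WSIs with ROI polygons,
# and labelled cohorts whose class-dependent second-order texture stands in
# for the pathological changes seen in dense tumour-cell areas.

# Fixed H&E-like hue anchors; intensity parameters rescale these
# multiplicatively, so texture differences live in density/contrast, not hue.
.BG_PALETTE <- c(230, 200, 220)
.NUC_PALETTE <- c(90, 60, 130)

#' Texture parameters for one tile class
#'
#' Describes the nucleus point process and noise used by
#' [generate_tile_image()]. Nuclei are placed by a homogeneous Poisson
#' process, so `nucleus_density * 512^2` is the expected nucleus count in a
#' standard tile.
#'
#' @param nucleus_density expected nuclei per square pixel (>= 0).
#' @param nucleus_radius_mean,nucleus_radius_sd nucleus radius distribution
#'   (pixels, truncated below at 1).
#' @param nucleus_intensity,background_intensity 8-bit anchor gray levels for
#'   the nuclear (hematoxylin) and background (eosin) colours; both in
#'   `[0, 255]`.
#' @param speckle_sd SD of additive Gaussian noise (gray levels); one noise
#'   field is shared by the three channels (channel-correlated sensor noise).
#' @return an object of class `texture_class_params`.
#' @export
texture_class_params <- function(nucleus_density = 280 / 512^2,
                                 nucleus_radius_mean = 6,
                                 nucleus_radius_sd = 1.5,
                                 nucleus_intensity = 90,
                                 background_intensity = 230,
                                 speckle_sd = 8) {
  if (nucleus_density < 0) stop("nucleus_density must be >= 0", call. = FALSE)
  if (nucleus_radius_mean <= 0) stop("nucleus_radius_mean must be > 0", call. = FALSE)
  if (nucleus_radius_sd < 0) stop("nucleus_radius_sd must be >= 0", call. = FALSE)
  ints <- c(nucleus_intensity, background_intensity)
  if (any(ints < 0 | ints > 255)) {
    stop("intensities must lie in [0, 255]", call. = FALSE)
  }
  if (speckle_sd < 0) stop("speckle_sd must be >= 0", call. = FALSE)
  structure(list(nucleus_density = nucleus_density,
                 nucleus_radius_mean = nucleus_radius_mean,
                 nucleus_radius_sd = nucleus_radius_sd,
                 nucleus_intensity = nucleus_intensity,
                 background_intensity = background_intensity,
                 speckle_sd = speckle_sd),
            class = "texture_class_params")
}

#' Class texture parameters at a given separation
#'
#' Maps a dimensionless `effect_size` to a pair of [texture_class_params()]:
#' the non-PR class keeps the baseline; the PR (poor-response) class gets
#' denser, slightly larger, darker nuclei and stronger speckle, scaled
#' linearly by `effect_size`. At `effect_size = 0` the two classes share one
#' distribution; `effect_size = 1` is the package's "strong separation"
#' reference condition.
#'
#' @param effect_size non-negative scale on the between-class differences.
#' @return list with elements `nonpr` and `pr`.
#' @export
class_params_for_effect <- function(effect_size = 1) {
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  base <- texture_class_params()
  pr <- texture_class_params(
    nucleus_density = base$nucleus_density * (1 + 0.45 * effect_size),
    nucleus_radius_mean = base$nucleus_radius_mean * (1 + 0.10 * effect_size),
    nucleus_radius_sd = base$nucleus_radius_sd,
    nucleus_intensity = clamp(base$nucleus_intensity * (1 - 0.15 * effect_size), 0, 255),
    background_intensity = base$background_intensity,
    speckle_sd = base$speckle_sd * (1 + 0.40 * effect_size)
  )
  list(nonpr = base, pr = pr)
}

scaled_colour <- function(palette, anchor, intensity) {
  clamp(palette * intensity / anchor, 0, 255)
}

# Render one textured field: nuclei placed by a homogeneous Poisson process
# and drawn as anti-aliased filled ellipses with random orientation/aspect
# (overlap allowed, composited multiplicatively via a transmittance field;
# only second-order statistics matter downstream). Must be called inside an
# RNG context; returns the H x W x 3 array.
render_texture <- function(height, width, params) {
  bg <- scaled_colour(.BG_PALETTE, 230, params$background_intensity)
  nuc <- scaled_colour(.NUC_PALETTE, 90, params$nucleus_intensity)
  n <- rpois(1, params$nucleus_density * height * width)
  if (n > 0) {
    cx <- runif(n, 0, width)
    cy <- runif(n, 0, height)
    radii <- pmax(1, rnorm(n, params$nucleus_radius_mean, params$nucleus_radius_sd))
    thetas <- runif(n, 0, pi)
    aspects <- runif(n, 1, 1.6)
    tr <- nuclei_transmittance_cpp(height, width, cx, cy, radii, thetas, aspects)
  } else {
    tr <- matrix(1, height, width)
  }
  noise <- if (params$speckle_sd > 0) {
    matrix(rnorm(height * width, 0, params$speckle_sd), height, width)
  } else matrix(0, 0, 0)
  img <- compose_channels_cpp(tr, noise, bg, nuc)
  attr(img, "n_nuclei") <- n
  img
}

#' Generate one synthetic H&E-like tile image
#'
#' Nuclei are placed by a homogeneous Poisson process with intensity
#' `params$nucleus_density` and drawn as anti-aliased filled ellipses over an
#' eosin-like background, then Gaussian speckle is added. Deterministic for a
#' fixed seed.
#'
#' @param params a [texture_class_params()] object.
#' @param seed integer seed.
#' @param size tile edge length in pixels (default 512, the pipeline's tile
#'   contract).
#' @return numeric `size x size x 3` array with values in `[0, 255]`; the
#'   realised Poisson nucleus count is attached as attribute `"n_nuclei"`.
#' @export
generate_tile_image <- function(params, seed, size = 512) {
  stopifnot(inherits(params, "texture_class_params"))
  withr::with_seed(as.integer(seed), render_texture(size, size, params))
}

#' Generate a pseudo whole-slide image with an ROI annotation
#'
#' Fills the interior of `roi_polygon` with nucleus texture and leaves the
#' exterior blank (white), emulating an annotated tumour region on a slide.
#'
#' @param width,height image dimensions in pixels.
#' @param roi_polygon n x 2 matrix of (x, y) vertices in 0-based pixel
#'   coordinates, inside the image bounds.
#' @param params a [texture_class_params()] object.
#' @param seed integer seed.
#' @return list with `image` (H x W x 3 array) and `annotation`
#'   (a [roi_annotation()]).
#' @export
generate_pseudo_wsi <- function(width, height, roi_polygon, params, seed) {
  poly <- check_polygon(roi_polygon)
  if (min(poly[, 1]) < 0 || max(poly[, 1]) > width ||
      min(poly[, 2]) < 0 || max(poly[, 2]) > height) {
    stop("roi_polygon must lie inside the image bounds", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    img <- render_texture(height, width, params)
    inside <- polygon_mask(poly, height, width)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[!inside] <- 255
      img[, , ch] <- plane
    }
    list(image = img,
         annotation = roi_annotation(list(poly), magnification = "x200"))
  })
}

# Table-1-style class-conditional covariate frequencies (primary dataset).
default_covariate_freqs <- function() {
  list(
    nonpr = list(age_mean = 56.0, age_sd = 11.4,
                 gender = c(male = 38, female = 23) / 61,
                 t_stage = c(T2 = 2, T3 = 23, T4 = 36) / 61,
                 n_stage = c(N0 = 6, N1 = 46, N2 = 9) / 61,
                 cea = c(normal = 30, abnormal = 31) / 61),
    pr = list(age_mean = 55.4, age_sd = 10.9,
              gender = c(male = 42, female = 17) / 59,
              t_stage = c(T2 = 1, T3 = 26, T4 = 32) / 59,
              n_stage = c(N0 = 17, N1 = 31, N2 = 11) / 59,
              cea = c(normal = 38, abnormal = 21) / 59)
  )
}

#' Configuration for a synthetic cohort
#'
#' Defaults are the package's reference study condition: 60 patients at the
#' source cohort's ~49% poor-response prevalence, 10-20 tumour tiles per
#' patient, strong texture separation (`effect_size = 1`) and 512-pixel
#' tiles.
#'
#' @param n_patients number of patients (>= 2).
#' @param pr_prevalence poor-response prevalence in (0, 1); default 59/120.
#' @param tiles_per_patient_min,tiles_per_patient_max bounds on the per-patient
#'   tile count (uniform between them).
#' @param effect_size passed to [class_params_for_effect()].
#' @param tile_size tile edge length in pixels.
#' @param seed root RNG seed; per-patient and per-tile substreams are derived
#'   from it by counter.
#' @param covariate_freqs class-conditional covariate frequencies; see
#'   `pathsig:::default_covariate_freqs` for the expected shape.
#' @return an object of class `synthetic_cohort_config`.
#' @export
cohort_config <- function(n_patients = 60,
                          pr_prevalence = 59 / 120,
                          tiles_per_patient_min = 10,
                          tiles_per_patient_max = 20,
                          effect_size = 1,
                          tile_size = 512,
                          seed = 1,
                          covariate_freqs = default_covariate_freqs()) {
  if (n_patients < 2) stop("n_patients must be >= 2", call. = FALSE)
  if (pr_prevalence <= 0 || pr_prevalence >= 1) {
    stop("pr_prevalence must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (tiles_per_patient_min < 1 || tiles_per_patient_max < tiles_per_patient_min) {
    stop("tile count bounds must satisfy 1 <= min <= max", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 pr_prevalence = pr_prevalence,
                 tiles_per_patient_min = as.integer(tiles_per_patient_min),
                 tiles_per_patient_max = as.integer(tiles_per_patient_max),
                 effect_size = effect_size,
                 tile_size = as.integer(tile_size),
                 seed = as.integer(seed),
                 covariate_freqs = covariate_freqs),
            class = "synthetic_cohort_config")
}

sample_cat <- function(n, freqs) {
  names(freqs)[sample.int(length(freqs), n, replace = TRUE, prob = freqs)]
}

#' Generate a labelled synthetic cohort
#'
#' Draws patient outcomes (binomial at the configured prevalence, redrawn in
#' the rare event a draw leaves a class empty), Table-1-like clinical
#' covariates sampled independently from class-conditional frequencies, and a
#' per-patient tile manifest. Tile pixel data are not materialised here:
#' each tile carries a derived seed and is regenerated on demand by
#' [cohort_tile_image()], keeping cohorts of hundreds of 512-pixel tiles out
#' of memory.
#'
#' @param config a [cohort_config()].
#' @return object of class `synthetic_cohort`: list with `patients`
#'   (data.frame: patient_id, label, age, gender, t_stage, n_stage, cea,
#'   n_tiles), `tiles` (data.frame: tile_id, patient_id, label, seed),
#'   `class_params`, and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  cp <- class_params_for_effect(config$effect_size)
  fq <- config$covariate_freqs
  n <- config$n_patients
  withr::with_seed(config$seed, {
    labels <- rbinom(n, 1, config$pr_prevalence)
    while (length(unique(labels)) < 2) {
      labels <- rbinom(n, 1, config$pr_prevalence)
    }
    cls <- ifelse(labels == 1, "pr", "nonpr")
    age <- numeric(n); gender <- character(n)
    t_stage <- character(n); n_stage <- character(n); cea <- character(n)
    for (g in c("nonpr", "pr")) {
      idx <- which(cls == g)
      if (!length(idx)) next
      age[idx] <- round(rnorm(length(idx), fq[[g]]$age_mean, fq[[g]]$age_sd), 1)
      gender[idx] <- sample_cat(length(idx), fq[[g]]$gender)
      t_stage[idx] <- sample_cat(length(idx), fq[[g]]$t_stage)
      n_stage[idx] <- sample_cat(length(idx), fq[[g]]$n_stage)
      cea[idx] <- sample_cat(length(idx), fq[[g]]$cea)
    }
    n_tiles <- sample(config$tiles_per_patient_min:config$tiles_per_patient_max,
                      n, replace = TRUE)
  })
  patient_id <- sprintf("P%03d", seq_len(n))
  patients <- data.frame(patient_id = patient_id,
                         label = ifelse(labels == 1, "PR", "non-PR"),
                         age = age, gender = gender, t_stage = t_stage,
                         n_stage = n_stage, cea = cea, n_tiles = n_tiles,
                         stringsAsFactors = FALSE)
  tiles <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(tile_id = sprintf("%s_T%02d", patient_id[i], seq_len(n_tiles[i])),
               patient_id = patient_id[i],
               label = patients$label[i],
               stringsAsFactors = FALSE)
  }))
  tiles$seed <- derive_seed(config$seed, seq_len(nrow(tiles)))
  structure(list(patients = patients, tiles = tiles,
                 class_params = cp, config = config),
            class = "synthetic_cohort")
}

#' Materialise one tile of a synthetic cohort
#'
#' @param cohort a [generate_cohort()] result.
#' @param tile_id a tile id from `cohort$tiles`.
#' @return the tile's RGB pixel array.
#' @export
cohort_tile_image <- function(cohort, tile_id) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  row <- cohort$tiles[cohort$tiles$tile_id == tile_id, ]
  if (nrow(row) != 1) stop("unknown tile_id: ", tile_id, call. = FALSE)
  params <- if (row$label == "PR") cohort$class_params$pr else cohort$class_params$nonpr
  generate_tile_image(params, row$seed, size = cohort$config$tile_size)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d patients (%d PR / %d non-PR), %d tiles of %dpx, effect_size=%g\n",
              nrow(x$patients), sum(x$patients$label == "PR"),
              sum(x$patients$label == "non-PR"), nrow(x$tiles),
              x$config$tile_size, x$config$effect_size))
  invisible(x)
}

#' Write an image as PNG
#'
#' @param img H x W (gray) or H x W x 3 array, values in `[0, 255]`.
#' @param path output file.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(clamp(img / 255, 0, 1), target = path)
}

#' Read a PNG into the package's 0-255 array convention
#'
#' @param path PNG file; gray images are expanded to 3 identical channels.
#' @return H x W x 3 numeric array in `[0, 255]`.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE] # drop alpha
  img * 255
}

#' Write cohort tables and tile images to disk
#'
#' Writes `cohort.csv` (one row per patient, tile ids comma-joined),
#' `tiles.csv` and, optionally, every tile as `{tile_id}.png`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @param images whether to render tile PNGs (slow for large cohorts).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, images = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pats <- cohort$patients
  pats$tile_ids <- vapply(pats$patient_id, function(p) {
    paste(cohort$tiles$tile_id[cohort$tiles$patient_id == p], collapse = ";")
  }, character(1))
  write.csv(pats, file.path(dir, "cohort.csv"), row.names = FALSE)
  write.csv(cohort$tiles, file.path(dir, "tiles.csv"), row.names = FALSE)
  if (images) {
    for (tid in cohort$tiles$tile_id) {
      write_image_png(cohort_tile_image(cohort, tid),
                      file.path(dir, paste0(tid, ".png")))
    }
  }
  invisible(dir)
}
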