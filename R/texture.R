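# 104-dimensional tile texture descriptor: luminance -> 64-level uniform
# quantization -> symmetric normalized GLCMs at distances {1,2} x angles
# {0,45,90,135} degrees -> 13 Haralick statistics per matrix.

.HARALICK_STATS <- c("asm", "contrast", "correlation", "variance", "idm",
                     "sum_average", "sum_variance", "sum_entropy", "entropy",
                     "diff_variance", "diff_entropy", "imc1", "imc2")

#' GLCM configuration
#'
#' The default (64 gray levels, distances 1 and 2, the four standard
#' directions, symmetric and normalized matrices, natural logs) yields
#' 13 statistics x 2 distances x 4 angles = 104 features per tile.
#'
#' @param levels number of gray levels G (>= 2); quantization is uniform over
#'   the fixed global range `[0, 255]`, never per-image min-max, so a tile's
#'   overall brightness does not leak into its texture.
#' @param distances positive integer pixel offsets.
#' @param angles subset of `c(0, 45, 90, 135)` degrees.
#' @return an object of class `glcm_config`.
#' @export
glcm_config <- function(levels = 64, distances = c(1, 2),
                        angles = c(0, 45, 90, 135)) {
  if (levels < 2) stop("levels must be >= 2", call. = FALSE)
  if (any(distances < 1 | distances != as.integer(distances))) {
    stop("distances must be positive integers", call. = FALSE)
  }
  if (!all(angles %in% c(0, 45, 90, 135))) {
    stop("angles must be drawn from {0, 45, 90, 135}", call. = FALSE)
  }
  structure(list(levels = as.integer(levels),
                 distances = as.integer(distances),
                 angles = as.integer(angles)),
            class = "glcm_config")
}

#' Convert an RGB image to luminance
#'
#' Rec. 601 luma: `0.299 R + 0.587 G + 0.114 B`, kept at full precision.
#'
#' @param rgb H x W x 3 numeric array in `[0, 255]`.
#' @return H x W numeric matrix.
#' @export
to_grayscale <- function(rgb) {
  assert_rgb(rgb)
  g <- 0.299 * rgb[, , 1, drop = TRUE] + 0.587 * rgb[, , 2, drop = TRUE] +
    0.114 * rgb[, , 3, drop = TRUE]
  if (is.null(dim(g))) g <- matrix(g, dim(rgb)[1], dim(rgb)[2])
  g
}

#' Quantize a gray image to G levels
#'
#' Uniform bins over the fixed range `[0, 255]`: bin `k = floor(v * G / 256)`,
#' with 255 mapping to the top bin.
#'
#' @param gray numeric matrix with values in `[0, 255]`.
#' @param levels number of gray levels G.
#' @return integer matrix with values in `[0, G-1]`.
#' @export
quantize_gray <- function(gray, levels = 64) {
  if (min(gray) < 0 || max(gray) > 255) {
    stop("gray values must lie in [0, 255]", call. = FALSE)
  }
  q <- floor(gray * levels / 256)
  storage.mode(q) <- "integer"
  q[q > levels - 1L] <- levels - 1L
  q
}

# Offset (dr, dc) for a distance/angle pair; rows grow downward.
angle_offset <- function(distance, angle) {
  d <- as.integer(distance)
  switch(as.character(angle),
         "0" = c(0L, d),
         "45" = c(-d, d),
         "90" = c(-d, 0L),
         "135" = c(-d, -d),
         stop("angle must be one of 0, 45, 90, 135", call. = FALSE))
}

#' Compute a symmetric normalized gray-level co-occurrence matrix
#'
#' Counts ordered pixel pairs at the offset implied by `(distance, angle)`,
#' symmetrizes (`C + t(C)`), and normalizes to sum 1. Pairs with either pixel
#' outside the image are excluded.
#'
#' @param qimg integer matrix from [quantize_gray()].
#' @param distance positive integer pixel distance.
#' @param angle one of 0, 45, 90, 135 (degrees).
#' @param levels number of gray levels G.
#' @return G x G numeric matrix summing to 1.
#' @export
compute_glcm <- function(qimg, distance, angle, levels = 64) {
  off <- angle_offset(distance, angle)
  storage.mode(qimg) <- "integer"
  cnt <- glcm_counts_cpp(qimg, as.integer(levels), off[1], off[2])
  m <- matrix(cnt, levels, levels)
  s <- sum(m)
  if (s == 0) stop("image smaller than the requested offset", call. = FALSE)
  m / s
}

# Per-G cache of index/weight matrices used by haralick13.
.glcm_cache <- new.env(parent = emptyenv())

glcm_weights <- function(G) {
  key <- as.character(G)
  w <- .glcm_cache[[key]]
  if (is.null(w)) {
    i <- matrix(0:(G - 1), G, G)          # row level index
    j <- t(i)
    w <- list(i = i, j = j, ij = i * j,
              diff2 = (i - j)^2,
              idm = 1 / (1 + (i - j)^2),
              sum_idx = i + j + 1L,       # 1-based bucket for i+j in 0..2G-2
              diff_idx = abs(i - j) + 1L) # 1-based bucket for |i-j| in 0..G-1
    .glcm_cache[[key]] <- w
  }
  w
}

entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p)) # convention 0*log(0) = 0
}

#' The 13 Haralick statistics of a GLCM
#'
#' Computes angular second moment, contrast, correlation, variance, inverse
#' difference moment, sum average/variance/entropy, entropy, difference
#' variance/entropy, and the two information measures of correlation, all
#' with natural logarithms and the `0*log(0) = 0` convention. Sum variance is
#' centred on the sum average. For a degenerate (zero-variance) matrix,
#' correlation is 1 and IMC1 = IMC2 = 0, the constant-image limit.
#'
#' @param p G x G symmetric matrix with non-negative entries summing to 1.
#' @return named numeric vector of length 13.
#' @export
haralick13 <- function(p) {
  if (!is.matrix(p) || nrow(p) != ncol(p)) stop("p must be square", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8) stop("p must be normalized (sum to 1)", call. = FALSE)
  if (max(abs(p - t(p))) > 1e-8) stop("p must be symmetric", call. = FALSE)
  G <- nrow(p)
  w <- glcm_weights(G)
  lev <- 0:(G - 1)
  px <- rowSums(p) # = colSums for symmetric p
  mu <- sum(lev * px)
  sigma2 <- sum((lev - mu)^2 * px)

  asm <- sum(p^2)
  contrast <- sum(w$diff2 * p)
  idm <- sum(w$idm * p)
  variance <- sigma2

  p_sum <- as.vector(rowsum(as.vector(p), as.vector(w$sum_idx))) # k = 0..2G-2
  ks <- 0:(2 * G - 2)
  sum_average <- sum(ks * p_sum)
  sum_variance <- sum((ks - sum_average)^2 * p_sum)
  sum_entropy <- entropy_nat(p_sum)

  p_diff <- as.vector(rowsum(as.vector(p), as.vector(w$diff_idx))) # k = 0..G-1
  kd <- seq_along(p_diff) - 1
  mu_d <- sum(kd * p_diff)
  diff_variance <- sum((kd - mu_d)^2 * p_diff)
  diff_entropy <- entropy_nat(p_diff)

  ent <- entropy_nat(p)

  if (sigma2 < .Machine$double.eps * G^2) {
    correlation <- 1
    imc1 <- 0
    imc2 <- 0
  } else {
    correlation <- (sum(w$ij * p) - mu^2) / sigma2
    hx <- entropy_nat(px)
    pxy <- outer(px, px)
    pos <- p > 0
    hxy1 <- -sum(p[pos] * log(pxy[pos]))
    pos2 <- pxy > 0
    hxy2 <- -sum(pxy[pos2] * log(pxy[pos2]))
    imc1 <- if (hx > 0) (ent - hxy1) / hx else 0
    imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  }

  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sum_average = sum_average,
    sum_variance = sum_variance, sum_entropy = sum_entropy, entropy = ent,
    diff_variance = diff_variance, diff_entropy = diff_entropy,
    imc1 = imc1, imc2 = imc2)
}

#' Canonical feature names for a GLCM configuration
#'
#' @param config a [glcm_config()].
#' @return character vector (`{stat}_d{distance}_a{angle}`), distance-major,
#'   then angle, then statistic; 104 names for the default configuration.
#' @export
feature_names <- function(config = glcm_config()) {
  unlist(lapply(config$distances, function(d) {
    lapply(config$angles, function(a) {
      sprintf("%s_d%d_a%d", .HARALICK_STATS, d, a)
    })
  }))
}

#' Extract the texture feature vector of one tile
#'
#' Luminance conversion, global-range quantization, one symmetric normalized
#' GLCM per distance/angle pair, and the 13 Haralick statistics of each:
#' 104 named values for the default configuration.
#'
#' @param tile H x W x 3 RGB array in `[0, 255]` (512 x 512 in the standard
#'   pipeline) or an H x W luminance matrix.
#' @param config a [glcm_config()].
#' @return named numeric vector, in [feature_names()] order.
#' @export
extract_features <- function(tile, config = glcm_config()) {
  gray <- if (is_rgb_array(tile)) to_grayscale(tile) else tile
  q <- quantize_gray(gray, config$levels)
  G <- config$levels
  offs <- do.call(rbind, lapply(config$distances, function(d) {
    do.call(rbind, lapply(config$angles, function(a) angle_offset(d, a)))
  }))
  cnt <- glcm_counts_cpp(q, G, offs[, 1], offs[, 2])
  out <- lapply(seq_len(nrow(offs)), function(k) {
    m <- matrix(cnt[, , k], G, G)
    s <- sum(m)
    if (s == 0) stop("image smaller than the requested offset", call. = FALSE)
    haralick13(m / s)
  })
  setNames(unlist(out), feature_names(config))
}

#' Feature table for a synthetic cohort
#'
#' Streams over the cohort's tile manifest, materialising each tile with
#' [cohort_tile_image()] and extracting its features, so pixel data never
#' accumulate in memory.
#'
#' @param cohort a [generate_cohort()] result.
#' @param config a [glcm_config()].
#' @return data.frame: tile_id, patient_id, label, then the feature columns.
#' @export
cohort_feature_table <- function(cohort, config = glcm_config()) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  feats <- matrix(NA_real_, nrow(cohort$tiles), length(feature_names(config)),
                  dimnames = list(NULL, feature_names(config)))
  for (i in seq_len(nrow(cohort$tiles))) {
    feats[i, ] <- extract_features(
      cohort_tile_image(cohort, cohort$tiles$tile_id[i]), config)
  }
  cbind(cohort$tiles[, c("tile_id", "patient_id", "label")],
        as.data.frame(feats))
}
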