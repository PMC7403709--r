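# Annotated-image tiling: minimum-bounding-rectangle crop of the ROI union,
# block-mean downsampling (x400 -> x200), non-overlapping 512 x 512 grid,
# and tile selection. All coordinates are 0-based (row, col) with half-open
# pixel intervals.

#' ROI annotation: one or more tumour-region polygons
#'
#' @param polygons a single n x 2 matrix or a list of them; vertices are
#'   (x, y) in 0-based pixel coordinates at the source magnification. Open
#'   rings are closed implicitly; each polygon needs >= 3 distinct vertices
#'   and positive area.
#' @param magnification source magnification tag, `"x400"` or `"x200"`.
#' @return an object of class `roi_annotation`.
#' @export
roi_annotation <- function(polygons, magnification = c("x400", "x200")) {
  magnification <- match.arg(magnification)
  if (is.matrix(polygons)) polygons <- list(polygons)
  polygons <- lapply(polygons, check_polygon)
  structure(list(polygons = polygons, magnification = magnification),
            class = "roi_annotation")
}

#' Serialize / read an ROI annotation as GeoJSON
#'
#' @param annotation a [roi_annotation()].
#' @param path file path.
#' @return `write_roi_geojson` returns `path` invisibly; `read_roi_geojson`
#'   returns a `roi_annotation`.
#' @export
write_roi_geojson <- function(annotation, path) {
  stopifnot(inherits(annotation, "roi_annotation"))
  feats <- lapply(annotation$polygons, function(p) {
    ring <- rbind(p, p[1, ])
    list(type = "Feature",
         properties = list(magnification = annotation$magnification),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(split(ring, row(ring))))))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_geojson
#' @export
read_roi_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  polys <- lapply(gj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(v) as.numeric(unlist(v))))
    ring
  })
  mag <- gj$features[[1]]$properties$magnification %||% "x400"
  roi_annotation(polys, magnification = mag)
}

#' Crop an image to the minimum bounding rectangle of its ROIs
#'
#' @param image H x W x 3 (or H x W) numeric array.
#' @param annotation a [roi_annotation()]; the union of its polygons defines
#'   the axis-aligned bounding rectangle.
#' @return list with `image` (the crop) and `offset` `c(row, col)`, the
#'   0-based position of the crop's origin in the source image.
#' @export
crop_bounding_rect <- function(image, annotation) {
  stopifnot(inherits(annotation, "roi_annotation"))
  d <- dim(image)
  H <- d[1]; W <- d[2]
  verts <- do.call(rbind, annotation$polygons)
  if (min(verts) < 0 || max(verts[, 1]) > W || max(verts[, 2]) > H) {
    stop("annotation polygons fall outside the image bounds", call. = FALSE)
  }
  r0 <- floor(min(verts[, 2])); r1 <- ceiling(max(verts[, 2]))
  c0 <- floor(min(verts[, 1])); c1 <- ceiling(max(verts[, 1]))
  sub <- if (length(d) == 3) {
    image[(r0 + 1):r1, (c0 + 1):c1, , drop = FALSE]
  } else {
    image[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE]
  }
  list(image = sub, offset = c(row = r0, col = c0))
}

#' Downsample an image by block averaging
#'
#' Each output pixel is the exact mean of the corresponding `factor x factor`
#' block (alias-free, deterministic, kept at full precision); output
#' dimensions are `floor(dim / factor)` and trailing remainders are dropped.
#' `factor = 2` maps x400 magnification to x200.
#'
#' @param image H x W or H x W x 3 numeric array.
#' @param factor positive integer downsampling factor.
#' @return downsampled array of the same arity.
#' @export
downsample_image <- function(image, factor = 2) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stop("factor must be a positive integer", call. = FALSE)
  if (factor == 1) return(image)
  block_mean <- function(m) {
    fh <- nrow(m) %/% factor; fw <- ncol(m) %/% factor
    if (fh == 0 || fw == 0) stop("image smaller than one block", call. = FALSE)
    m <- m[seq_len(fh * factor), seq_len(fw * factor), drop = FALSE]
    out <- t(rowsum(t(rowsum(m, rep(seq_len(fh), each = factor))),
                    rep(seq_len(fw), each = factor))) / factor^2
    dimnames(out) <- NULL
    out
  }
  if (length(dim(image)) == 3) {
    planes <- lapply(seq_len(dim(image)[3]), function(ch) block_mean(image[, , ch]))
    array(unlist(planes), dim = c(dim(planes[[1]]), length(planes)))
  } else {
    block_mean(image)
  }
}

#' Tile an image into a non-overlapping grid
#'
#' The grid is anchored at the crop origin (0, 0); partial right/bottom tiles
#' are dropped so every tile is exactly `tile_size` square. Per-tile tissue
#' fraction is the share of pixels that are non-background (luminance <= 220)
#' and, when `mask` is supplied, inside the ROI mask.
#'
#' @param image H x W x 3 (or H x W) numeric array in `[0, 255]`.
#' @param tile_size tile edge length (default 512).
#' @param patient_id optional id stamped into tile ids.
#' @param mask optional logical H x W matrix (TRUE = inside ROI).
#' @return object of class `tile_grid`: list with `tiles` (data.frame:
#'   tile_id, row, col, r0, r1, c0, c1 half-open 0-based pixel bounds,
#'   tissue_fraction), `tile_size`, and the retained `image`.
#' @export
tile_image <- function(image, tile_size = 512, patient_id = NULL, mask = NULL) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  tile_size <- as.integer(tile_size)
  nr <- H %/% tile_size; nc <- W %/% tile_size
  lum <- if (length(d) == 3) to_grayscale(image) else image
  tissue <- lum <= 220
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(tissue)))
    tissue <- tissue & mask
  }
  if (nr == 0 || nc == 0) {
    warning("image smaller than one tile; empty grid", call. = FALSE)
    tiles <- data.frame(tile_id = character(0), row = integer(0), col = integer(0),
                        r0 = integer(0), r1 = integer(0), c0 = integer(0),
                        c1 = integer(0), tissue_fraction = numeric(0))
  } else {
    grid <- expand.grid(row = 0:(nr - 1), col = 0:(nc - 1))
    grid <- grid[order(grid$row, grid$col), ]
    tiles <- data.frame(
      tile_id = sprintf("%s_%d_%d", patient_id %||% "tile", grid$row, grid$col),
      row = grid$row, col = grid$col,
      r0 = grid$row * tile_size, r1 = (grid$row + 1) * tile_size,
      c0 = grid$col * tile_size, c1 = (grid$col + 1) * tile_size,
      stringsAsFactors = FALSE)
    tiles$tissue_fraction <- vapply(seq_len(nrow(tiles)), function(i) {
      mean(tissue[(tiles$r0[i] + 1):tiles$r1[i], (tiles$c0[i] + 1):tiles$c1[i]])
    }, numeric(1))
    rownames(tiles) <- NULL
  }
  structure(list(tiles = tiles, tile_size = tile_size, image = image),
            class = "tile_grid")
}

#' Extract the pixels of one tile from a grid
#'
#' @param grid a [tile_image()] result.
#' @param tile_id a tile id present in `grid$tiles`.
#' @return the tile's pixel array.
#' @export
get_tile <- function(grid, tile_id) {
  stopifnot(inherits(grid, "tile_grid"))
  t <- grid$tiles[grid$tiles$tile_id == tile_id, ]
  if (nrow(t) != 1) stop("unknown tile_id: ", tile_id, call. = FALSE)
  if (length(dim(grid$image)) == 3) {
    grid$image[(t$r0 + 1):t$r1, (t$c0 + 1):t$c1, , drop = FALSE]
  } else {
    grid$image[(t$r0 + 1):t$r1, (t$c0 + 1):t$c1, drop = FALSE]
  }
}

#' Select tiles for feature extraction
#'
#' `"explicit"` mode replays a curated tile list (the pathologists' manual
#' choice); `"tissue_fraction"` mode is the automated surrogate keeping tiles
#' whose tissue fraction meets a threshold.
#'
#' @param grid a [tile_image()] result.
#' @param mode `"explicit"` or `"tissue_fraction"`.
#' @param tile_ids ids to keep (explicit mode; order preserved).
#' @param threshold minimum tissue fraction (default 0.8).
#' @return the selected rows of `grid$tiles`.
#' @export
select_tiles <- function(grid, mode = c("explicit", "tissue_fraction"),
                         tile_ids = NULL, threshold = 0.8) {
  stopifnot(inherits(grid, "tile_grid"))
  mode <- match.arg(mode)
  tiles <- grid$tiles
  if (mode == "explicit") {
    if (is.null(tile_ids)) stop("explicit mode needs tile_ids", call. = FALSE)
    missing <- setdiff(tile_ids, tiles$tile_id)
    if (length(missing)) {
      stop("tile ids absent from grid: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    out <- tiles[match(tile_ids, tiles$tile_id), ]
  } else {
    out <- tiles[tiles$tissue_fraction >= threshold, ]
  }
  rownames(out) <- NULL
  out
}
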