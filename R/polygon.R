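# Polygon utilities for ROI annotations. Vertices are n x 2 matrices with
# columns (x, y) in 0-based continuous pixel coordinates (x = column,
# y = row); pixel (r, c) covers the half-open square [r, r+1) x [c, c+1).

check_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (!is.numeric(poly) || ncol(poly) != 2) {
    stop("polygon must be an n x 2 numeric matrix of (x, y) vertices",
         call. = FALSE)
  }
  # drop an explicit closing vertex
  n <- nrow(poly)
  if (n >= 2 && all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  if (nrow(poly) < 3) stop("polygon needs at least 3 distinct vertices", call. = FALSE)
  if (polygon_area(poly) <= 0) stop("polygon has empty interior", call. = FALSE)
  poly
}

#' Polygon area by the shoelace formula
#'
#' @param poly n x 2 matrix of (x, y) vertices (open or closed ring).
#' @return area in square pixels.
#' @export
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (n >= 2 && all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  n <- nrow(poly)
  if (n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Even-odd scanline rasterization: TRUE where the pixel centre (r+0.5, c+0.5)
# lies inside any polygon. No spatial package in scope provides this fill.
polygon_mask <- function(polygons, height, width) {
  if (is.matrix(polygons)) polygons <- list(polygons)
  mask <- matrix(FALSE, height, width)
  for (poly in polygons) {
    poly <- check_polygon(poly)
    x <- poly[, 1]; y <- poly[, 2]
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    keep <- y != yn
    x0 <- x[keep]; y0 <- y[keep]; x1 <- xn[keep]; y1 <- yn[keep]
    rmin <- max(0L, floor(min(y)))
    rmax <- min(height - 1L, ceiling(max(y)))
    if (rmax < rmin) next
    for (r in rmin:rmax) {
      yc <- r + 0.5
      hit <- (pmin(y0, y1) <= yc) & (yc < pmax(y0, y1))
      if (!any(hit)) next
      xs <- sort(x0[hit] + (yc - y0[hit]) / (y1[hit] - y0[hit]) * (x1[hit] - x0[hit]))
      for (i in seq(1, length(xs) - 1, by = 2)) {
        c0 <- max(0L, ceiling(xs[i] - 0.5))
        c1 <- min(width - 1L, floor(xs[i + 1] - 0.5))
        if (c1 >= c0) mask[r + 1L, (c0 + 1L):(c1 + 1L)] <- TRUE
      }
    }
  }
  mask
}
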