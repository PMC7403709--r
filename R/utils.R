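#' Derive a reproducible child seed from a root seed
#'
#' One root seed fans out to per-stage, per-patient and per-tile substreams by
#' counter, so artifacts are identical whether stages run monolithically or
#' one at a time, and cohort tiles can be regenerated individually.
#'
#' @param root integer root seed.
#' @param counter vector of non-negative integer stream indices; one seed is
#'   returned per element.
#' @return integer seed(s) in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(root, counter) {
  stopifnot(is.numeric(root), length(root) == 1, is.numeric(counter))
  m <- 2147483647 # 2^31 - 1, Lehmer modulus
  s0 <- (abs(as.double(root)) %% m) + 1
  vapply(as.double(counter), function(k) {
    s <- (s0 * 48271 + k + 1) %% m
    s <- (s * 48271 + 1) %% m # second mixing round decorrelates adjacent k
    as.integer(s %% (m - 2)) + 1L
  }, integer(1))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_rgb_array <- function(x) {
  is.array(x) && length(dim(x)) == 3 && dim(x)[3] == 3 && is.numeric(x)
}

assert_rgb <- function(x, what = "image") {
  if (!is_rgb_array(x)) {
    stop(what, " must be a numeric H x W x 3 array with values in [0, 255]",
         call. = FALSE)
  }
  invisible(x)
}

# Normalize labels to a 0/1 integer vector (1 = positive / "PR") and keep the
# level names around for reporting.
as_binary_label <- function(labels, positive = NULL) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  u <- sort(unique(labels))
  if (length(u) < 2) stop("labels must contain two classes", call. = FALSE)
  if (length(u) > 2) stop("labels must be binary", call. = FALSE)
  if (is.null(positive)) {
    positive <- if ("PR" %in% u) "PR" else u[2]
  }
  y <- as.integer(labels == positive)
  attr(y, "positive") <- as.character(positive)
  y
}
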