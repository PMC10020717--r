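#' Rasterize a cross-section boundary to a binary shape image
#'
#' Renders the lumen polygon as binary pixel occupancy on a square grid over
#' a fixed physical window centered at the section origin and oriented by
#' the section's rotation-minimizing frame. The fixed window preserves
#' absolute size information: the shape code must encode more than scale.
#'
#' @param section one element of `case_geometry$sections` (needs
#'   `boundary2d`), or an n x 2 matrix of in-plane boundary vertices in mm.
#' @param grid_size pixels per side (default 68, the autoencoder input size).
#' @param window_mm physical window side length, mm (default 50).
#' @return a `shape_image`: `grid_size` x `grid_size` 0/1 matrix with
#'   attributes `window_mm` and `section_index`.
#' @export
#' @examples
#' img <- rasterize_section(ellipse_boundary(pi * 100), 68, 50)
#' mean(img) # about pi * 10^2 / 50^2
rasterize_section <- function(section, grid_size = 68L, window_mm = 50) {
  b2 <- if (is.matrix(section)) section else section$boundary2d
  idx <- if (is.matrix(section)) NA_integer_ else section$index
  if (is.null(b2) || nrow(b2) < 3) abort("empty or degenerate section boundary")
  ext <- max(abs(b2))
  if (ext > window_mm / 2) {
    abort(sprintf("boundary extent %.1f mm exceeds raster window of %.1f mm",
                  2 * ext, window_mm))
  }
  px <- window_mm / grid_size
  centers <- seq(-window_mm / 2 + px / 2, window_mm / 2 - px / 2, length.out = grid_size)
  gx <- rep(centers, times = grid_size)
  gy <- rep(centers, each = grid_size)
  occ <- points_in_polygon(gx, gy, b2)
  img <- matrix(as.numeric(occ), grid_size, grid_size)
  structure(img, window_mm = window_mm, section_index = idx,
            class = c("shape_image", "matrix", "array"))
}

# Vectorized even-odd (crossing number) point-in-polygon test.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- poly[c(2:n, 1), 1]; y2 <- poly[c(2:n, 1), 2]
  inside <- logical(length(px))
  for (e in seq_len(n)) {
    crosses <- (y1[e] > py) != (y2[e] > py)
    if (any(crosses)) {
      xint <- x1[e] + (py[crosses] - y1[e]) * (x2[e] - x1[e]) / (y2[e] - y1[e])
      hit <- px[crosses] < xint
      inside[crosses] <- xor(inside[crosses], hit)
    }
  }
  inside
}

#' Intersection-over-union of two binary shape images
#'
#' Images are thresholded at `threshold` before comparison.
#'
#' @param a,b numeric matrices of equal size (values in \[0, 1\]).
#' @param threshold binarization threshold.
#' @return IoU in \[0, 1\]; defined as 1 when both images are empty.
#' @export
shape_iou <- function(a, b, threshold = 0.5) {
  A <- a >= threshold
  B <- b >= threshold
  u <- sum(A | B)
  if (u == 0) return(1)
  sum(A & B) / u
}

#' @export
print.shape_image <- function(x, ...) {
  cat("<shape_image>", nrow(x), "x", ncol(x), "window",
      attr(x, "window_mm"), "mm, occupied", round(mean(x), 4), "\n")
  invisible(x)
}
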