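#' Canonicalize four corner points
#'
#' Sorts corners by angle around their centroid and rotates the cycle so it
#' starts at the top-left point (smallest `x + y`), yielding the order
#' top-left, top-right, bottom-right, bottom-left regardless of user input
#' order (image convention: y grows downward).
#'
#' @param quad 4x2 numeric matrix of `(x, y)` pixel coordinates.
#' @return 4x2 matrix in canonical order, class `quad_corners`.
#' @export
as_quad <- function(quad) {
  quad <- matrix(as.numeric(quad), 4, 2,
                 dimnames = list(NULL, c("x", "y")))
  ctr <- colMeans(quad)
  ord <- order(atan2(quad[, 2] - ctr[2], quad[, 1] - ctr[1]))
  quad <- quad[ord, , drop = FALSE]   # counterclockwise in image coords
  start <- which.min(quad[, 1] + quad[, 2])
  quad <- quad[((seq_len(4) + start - 2) %% 4) + 1, , drop = FALSE]
  if (!is_convex(quad)) {
    abort("corner points do not form a convex quadrilateral",
          class = "topotype_domain_error")
  }
  structure(quad, class = c("quad_corners", "matrix"))
}

is_convex <- function(quad) {
  v <- rbind(quad, quad[1:2, , drop = FALSE])
  cr <- numeric(4)
  for (i in 1:4) {
    a <- v[i + 1, ] - v[i, ]; b <- v[i + 2, ] - v[i + 1, ]
    cr[i] <- a[1] * b[2] - a[2] * b[1]
  }
  all(cr > 1e-9) || all(cr < -1e-9)
}

frame_corners <- function(n) {
  as_quad(rbind(c(1, 1), c(n, 1), c(n, n), c(1, n)))
}

#' Estimate the 3x3 homography mapping one quad to another
#'
#' Standard four-point direct linear estimation: the eight corner
#' correspondences give eight linear equations in the eight unknowns of
#' `H` (with `h33 = 1`), solved exactly. The returned matrix maps each
#' source corner onto its target corner to numerical precision.
#'
#' @param src,dst Source and destination corners (anything accepted by
#'   [as_quad()]; correspondences follow the canonical corner order).
#' @return A 3x3 matrix of class `homography`, normalized so `h33 = 1`.
#' @export
#' @examples
#' H <- estimate_homography(rbind(c(0,0), c(1,0), c(1,1), c(0,1)),
#'                          rbind(c(2,1), c(3,1), c(3,2), c(2,2)))
estimate_homography <- function(src, dst) {
  src <- as_quad(src); dst <- as_quad(dst)
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u; b[2 * i] <- v
  }
  h <- tryCatch(solve(A, b), error = function(e) {
    abort("degenerate corner geometry (collinear points?)",
          class = "topotype_domain_error", parent = e)
  })
  H <- matrix(c(h, 1), 3, 3, byrow = TRUE)
  structure(H, class = c("homography", "matrix"))
}

#' Apply a homography to points
#'
#' @param H A `homography`.
#' @param pts m x 2 matrix of `(x, y)` points.
#' @return m x 2 matrix of mapped, dehomogenized points.
#' @export
apply_homography <- function(H, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  P <- cbind(pts, 1) %*% t(unclass(H))
  P[, 1:2, drop = FALSE] / P[, 3]
}

# bilinear sampling of an n x m (x channels) image array at fractional
# pixel coordinates; outside the image returns `fill`
bilinear_sample <- function(img, x, y, fill = 0) {
  d <- dim(img)
  h <- d[1]; w <- d[2]; nc <- if (length(d) == 3) d[3] else 1
  eps <- 1e-6
  ok <- x > 1 - eps & x < w + eps & y > 1 - eps & y < h + eps
  xc <- pmin(pmax(x, 1), w); yc <- pmin(pmax(y, 1), h)
  x0c <- pmin(floor(xc), w - 1); y0c <- pmin(floor(yc), h - 1)
  fx <- xc - x0c; fy <- yc - y0c
  out <- matrix(fill, length(x), nc)
  for (ch in seq_len(nc)) {
    plane <- if (length(d) == 3) img[, , ch] else img
    i00 <- plane[cbind(y0c, x0c)]
    i01 <- plane[cbind(y0c, x0c + 1)]
    i10 <- plane[cbind(y0c + 1, x0c)]
    i11 <- plane[cbind(y0c + 1, x0c + 1)]
    v <- (1 - fy) * ((1 - fx) * i00 + fx * i01) +
      fy * ((1 - fx) * i10 + fx * i11)
    v[!ok] <- fill
    out[, ch] <- v
  }
  out
}

#' Warp a captured image into the canonical zone-aligned frame
#'
#' Given the four corner points of the (possibly perspective-distorted)
#' topogram in the capture image, estimates the homography from the
#' canonical `n` x `n` frame to the capture and resamples by inverse
#' mapping with bilinear interpolation, so the 3/5/7-mm zone rings land at
#' their canonical radii.
#'
#' @param image n x m x 3 RGB array in `[0,1]` (or a matrix for one
#'   channel).
#' @param src Corner points of the topogram frame in the capture image.
#' @param n Output side in pixels.
#' @param fill Value used outside the source quad.
#' @param margin Corners may poke up to this many pixels outside the
#'   capture (the off-frame part samples as `fill`); beyond it the corners
#'   are treated as erroneous input.
#' @return n x n (x 3) array.
#' @export
warp_to_canonical <- function(image, src, n = 256, fill = 0,
                              margin = 0.25 * min(dim(image)[1:2])) {
  d <- dim(image)
  src <- as_quad(src)
  if (any(src[, 1] < 0.5 - margin | src[, 1] > d[2] + 0.5 + margin |
          src[, 2] < 0.5 - margin | src[, 2] > d[1] + 0.5 + margin)) {
    abort("corner points fall outside the capture image",
          class = "topotype_domain_error")
  }
  H <- estimate_homography(frame_corners(n), src)
  gx <- rep(seq_len(n), each = n)    # output x (column)
  gy <- rep(seq_len(n), times = n)   # output y (row)
  sp <- apply_homography(H, cbind(gx, gy))
  nc <- if (length(d) == 3) d[3] else 1
  sampled <- bilinear_sample(image, sp[, 1], sp[, 2], fill = fill)
  if (nc == 1) {
    matrix(sampled[, 1], n, n)
  } else {
    array(sampled, dim = c(n, n, nc))
  }
}

#' Convert an RGB raster to HSV
#'
#' Standard hexcone conversion (via [grDevices::rgb2hsv()]): hue in degrees
#' `[0, 360)`, saturation and value in `[0, 1]`. Achromatic pixels get hue
#' 0 by convention.
#'
#' @param image n x m x 3 RGB array in `[0,1]` (8-bit quantized or not).
#' @return An `hsv_image`: n x m x 3 array with planes hue (degrees),
#'   saturation, value.
#' @export
rgb_to_hsv_image <- function(image) {
  d <- dim(image)
  stopifnot(length(d) == 3, d[3] == 3)
  m <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
             as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  out <- array(0, dim = d)
  out[, , 1] <- matrix(hsv[1, ] * 360, d[1], d[2])
  out[, , 2] <- matrix(hsv[2, ], d[1], d[2])
  out[, , 3] <- matrix(hsv[3, ], d[1], d[2])
  structure(out, class = c("hsv_image", "array"))
}

#' Convert an HSV image back to RGB
#'
#' @param hsv An `hsv_image` (hue degrees, saturation, value).
#' @return n x m x 3 RGB array in `[0,1]`.
#' @export
hsv_to_rgb_image <- function(hsv) {
  d <- dim(hsv)
  hex <- grDevices::hsv(as.vector(hsv[, , 1]) / 360,
                        as.vector(hsv[, , 2]), as.vector(hsv[, , 3]))
  rgb <- grDevices::col2rgb(hex) / 255
  out <- array(0, dim = d)
  for (ch in 1:3) out[, , ch] <- matrix(rgb[ch, ], d[1], d[2])
  out
}

#' Mean radial misalignment of the zone rings in a canonical frame
#'
#' Detects the white ring-overlay pixels of a rectified topogram and
#' measures the mean absolute radial distance between each detected ring
#' pixel and the nearest expected 3/5/7-mm radius. A perfectly rectified
#' synthetic render scores (near) zero; large values signal that the
#' capture should be re-taken with the zones properly coincident.
#'
#' @param canonical n x n x 3 RGB array in the canonical frame.
#' @param expected_zones_px Expected ring radii in pixels.
#' @param tol Pixels; ring pixels farther than this from every expected
#'   radius still count toward the error, but if fewer than 50 overlay
#'   pixels are found at all a quality-check error is raised.
#' @return Mean radial error in pixels.
#' @export
zone_alignment_error <- function(canonical, expected_zones_px, tol = 20) {
  n <- dim(canonical)[1]
  near_white <- canonical[, , 1] > 0.9 & canonical[, , 2] > 0.9 &
    canonical[, , 3] > 0.9
  if (sum(near_white) < 50) {
    abort("zone rings undetectable; recapture the image",
          class = "topotype_quality_error")
  }
  ctr <- (n + 1) / 2
  idx <- which(near_white, arr.ind = TRUE)
  rpx <- sqrt((idx[, 2] - ctr)^2 + (idx[, 1] - ctr)^2)
  # ignore the axis marks beyond the outer ring
  rpx <- rpx[rpx < max(expected_zones_px) + 1.5]
  d <- vapply(rpx, function(r) min(abs(r - expected_zones_px)), numeric(1))
  mean(pmin(d, tol))
}
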