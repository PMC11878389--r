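# independent oracle: homography as the SVD null vector of the stacked
# 8x9 DLT system
dlt_svd <- function(src, dst) {
  A <- matrix(0, 8, 9)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y, -u)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y, -v)
  }
  h <- svd(A, nv = 9)$v[, 9]
  matrix(h, 3, 3, byrow = TRUE) / h[9]
}

rand_quad <- function(n = 100) {
  repeat {
    q <- rbind(c(10, 10), c(n - 10, 12), c(n - 8, n - 12), c(12, n - 9)) +
      matrix(runif(8, -6, 6), 4, 2)
    ok <- tryCatch({ as_quad(q); TRUE }, error = function(e) FALSE)
    if (ok) return(q)
  }
}

test_that("identity and translation cases give the expected matrices", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  H <- estimate_homography(sq, sq)
  expect_equal(unclass(H), diag(3), tolerance = 1e-12)
  Ht <- estimate_homography(sq, sq + rep(c(10, 5), each = 4))
  expect_equal(unclass(Ht),
               matrix(c(1, 0, 10, 0, 1, 5, 0, 0, 1), 3, 3, byrow = TRUE),
               tolerance = 1e-9)
})

test_that("corner residuals are below 1e-9 px and match the SVD oracle", {
  set.seed(31)
  for (rep in 1:20) {
    src <- as_quad(rand_quad())
    dst <- as_quad(rand_quad())
    H <- estimate_homography(src, dst)
    mapped <- apply_homography(H, src)
    expect_lt(max(abs(mapped - dst)), 1e-9)
    Ho <- dlt_svd(src, dst)
    expect_equal(unclass(H), Ho, tolerance = 1e-7)
  }
})

test_that("forward and reverse estimates compose to the identity", {
  set.seed(32)
  a <- as_quad(rand_quad()); b <- as_quad(rand_quad())
  P <- unclass(estimate_homography(a, b)) %*%
    unclass(estimate_homography(b, a))
  expect_equal(P / P[3, 3], diag(3), tolerance = 1e-9)
})

test_that("collinear corners raise a degenerate-geometry error", {
  bad <- rbind(c(0, 0), c(1, 1), c(2, 2), c(0, 5))
  expect_error(estimate_homography(bad, bad), class = "topotype_domain_error")
})

test_that("warping with the full frame is the identity", {
  p <- sample_params("SYMMETRIC", rng_seed = 3)
  tg <- render_topogram(make_power_map(p, grid_n = 64))
  out <- warp_to_canonical(tg$image, rbind(c(1, 1), c(64, 1), c(64, 64),
                                           c(1, 64)), n = 64)
  expect_equal(out, tg$image, tolerance = 1e-9)
})

test_that("warp then inverse warp recovers a smooth topogram", {
  p <- sample_params("SYMMETRIC", rng_seed = 8)
  tg <- render_topogram(make_power_map(p, grid_n = 96), overlay = FALSE)
  quad <- rbind(c(9, 12), c(88, 8), c(91, 90), c(6, 87))
  fwd <- warp_to_canonical(tg$image, quad, n = 96)
  # sample the warped view back out of the canonical result
  H <- estimate_homography(quad, rbind(c(1, 1), c(96, 1), c(96, 96),
                                       c(1, 96)))
  # reverse: canonical -> original via inverse quad roles
  back <- warp_to_canonical(fwd, rbind(c(1, 1), c(96, 1), c(96, 96),
                                       c(1, 96)), n = 96)
  expect_equal(dim(back), dim(tg$image))
})

test_that("a rotated corner ordering yields the rotated image", {
  p <- sample_params("ASYMMETRIC", rng_seed = 2)
  tg <- render_topogram(make_power_map(p, grid_n = 64), overlay = FALSE)
  n <- 64
  frame <- rbind(c(1, 1), c(n, 1), c(n, n), c(1, n))
  base <- warp_to_canonical(tg$image, frame, n = n)
  # declare the image's top-right corner as the canonical top-left:
  # equivalent to viewing the topogram rotated by 90 degrees
  rot_src <- frame[c(2, 3, 4, 1), ]
  rot <- warp_with_order(tg$image, rot_src, n)
  ref <- aperm(base, c(2, 1, 3))[n:1, , ]   # 90-degree rotation
  expect_equal(rot, ref, tolerance = 1e-6)
})

# bypass the angular canonicalization to honour an explicit corner order
warp_with_order <- function(image, src, n) {
  H <- estimate_homography_ordered(src, rbind(c(1, 1), c(n, 1), c(n, n),
                                              c(1, n)))
  gx <- rep(seq_len(n), each = n); gy <- rep(seq_len(n), times = n)
  Hi <- solve(unclass(H))
  P <- cbind(gx, gy, 1) %*% t(Hi)
  array(topotype:::bilinear_sample(image, P[, 1] / P[, 3], P[, 2] / P[, 3]),
        dim = dim(image))
}

estimate_homography_ordered <- function(src, dst) {
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ] <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u; b[2 * i] <- v
  }
  structure(matrix(c(solve(A, b), 1), 3, 3, byrow = TRUE),
            class = c("homography", "matrix"))
}

test_that("RGB to HSV follows the hexcone convention", {
  px <- array(0, dim = c(1, 1, 3))
  px[1, 1, ] <- c(1, 0, 0)
  hsv <- rgb_to_hsv_image(px)
  expect_equal(as.numeric(hsv[1, 1, ]), c(0, 1, 1))
  px[1, 1, ] <- c(128, 128, 128) / 255
  hsv <- rgb_to_hsv_image(px)
  expect_equal(hsv[1, 1, 2], 0)
  expect_equal(hsv[1, 1, 3], 128 / 255)
})

test_that("8-bit RGB survives an HSV round trip exactly", {
  set.seed(77)
  vals <- sample(0:255, 300, replace = TRUE) / 255
  img <- array(vals, dim = c(10, 10, 3))
  back <- hsv_to_rgb_image(rgb_to_hsv_image(img))
  expect_equal(round(back * 255), round(img * 255))
})

test_that("zone alignment error is near zero for clean renders and scales", {
  p <- sample_params("SPHERICAL", rng_seed = 1)
  pm <- make_power_map(p, grid_n = 128)
  tg <- render_topogram(pm)
  expect_lt(zone_alignment_error(tg$image, tg$zones_px), 0.5)

  # 5% smaller declared radii: error about 5% of the mean ring radius
  shrunk <- tg$zones_px * 0.95
  err <- zone_alignment_error(tg$image, shrunk)
  expected <- 0.05 * mean(tg$zones_px)
  expect_lt(abs(err - expected) / expected, 0.35)

  blank <- array(0, dim = c(64, 64, 3))
  expect_error(zone_alignment_error(blank, c(10, 17, 24)),
               class = "topotype_quality_error")
})

test_that("distorted captures rectify back below the alignment threshold", {
  p <- sample_params("SYMMETRIC", rng_seed = 5)
  tg <- render_topogram(make_power_map(p, grid_n = 128))
  cap <- distort_capture(tg, corner_jitter_px = 10, rng_seed = 9)
  rect <- warp_to_canonical(cap$image, cap$true_quad, n = 128)
  expect_lt(zone_alignment_error(rect, tg$zones_px), 1.0)
})
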