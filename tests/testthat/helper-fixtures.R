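# Small shared fixtures; everything is generated in code.

noiseless_policy <- function() {
  pol <- default_variant_policy()
  pol$noise_sd <- 0
  pol
}

# a tiny bank plan for classifier tests (fast to build)
tiny_counts <- function(n = 8) {
  stats::setNames(rep(n, 4), CLASS_LABELS)
}

# reference confusion counts used across evaluate tests
ref_cm <- function() reference_confusion()

expect_same_hash <- function(a, b) {
  expect_identical(object_hash(a), object_hash(b))
}

deg2rad_t <- function(d) d * pi / 180

# symmetric Hausdorff distance between two point sets
hausdorff <- function(a, b) {
  dd <- function(p, q) {
    mins <- vapply(seq_len(nrow(p)), function(i) {
      min(sqrt((q[, 1] - p[i, 1])^2 + (q[, 2] - p[i, 2])^2))
    }, numeric(1))
    max(mins)
  }
  max(dd(a, b), dd(b, a))
}

new_contour_set_t <- function(polys) {
  topotype:::new_contour_set(polys)
}

# estimate a homography honouring an explicit corner order (bypasses the
# angular canonicalization), as an independent warp route for symmetry
# tests
estimate_homography_ordered <- function(src, dst) {
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ] <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u; b[2 * i] <- v
  }
  matrix(c(solve(A, b), 1), 3, 3, byrow = TRUE)
}

warp_with_order <- function(image, src, n) {
  H <- estimate_homography_ordered(src, rbind(c(1, 1), c(n, 1), c(n, n),
                                              c(1, n)))
  gx <- rep(seq_len(n), each = n); gy <- rep(seq_len(n), times = n)
  Hi <- solve(H)
  P <- cbind(gx, gy, 1) %*% t(Hi)
  array(topotype:::bilinear_sample(image, P[, 1] / P[, 3], P[, 2] / P[, 3]),
        dim = dim(image))
}
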