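#' Simulate a perspective-distorted smartphone capture of a topogram
#'
#' Jitters the four frame corners by up to `corner_jitter_px` in each
#' coordinate, builds the projective warp that carries the canonical frame
#' onto the jittered quad, and resamples the rendered topogram through it
#' (optionally adding a brightness change and box blur). The jittered quad
#' is returned as ground truth, so rectifying the capture with it recovers
#' the original view.
#'
#' With `corner_jitter_px = 0` and no photometrics the output is identical
#' to the input and the quad equals the frame corners. Same seed, same
#' output.
#'
#' @param topogram A `topogram` (or an n x n x 3 array).
#' @param corner_jitter_px Maximum corner displacement, pixels.
#' @param photometric List with `brightness` (max relative change, e.g.
#'   0.1) and `blur` (box-blur passes, integer).
#' @param rng_seed Integer seed.
#' @param max_tries Re-draw attempts if the jittered quad is non-convex.
#' @return A list: `image` (n x n x 3), `true_quad` (`quad_corners`),
#'   `seed`.
#' @export
distort_capture <- function(topogram, corner_jitter_px = 12,
                            photometric = list(brightness = 0, blur = 0),
                            rng_seed = 0, max_tries = 10) {
  img <- if (inherits(topogram, "topogram")) topogram$image else topogram
  n <- dim(img)[1]
  base <- unclass(frame_corners(n))

  if (corner_jitter_px == 0) {
    quad <- frame_corners(n)
    out <- img
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(split_seed(rng_seed, "capture"))
    quad <- NULL
    for (try in seq_len(max_tries)) {
      cand <- base + matrix(runif(8, -corner_jitter_px, corner_jitter_px), 4, 2)
      if (is_convex(cand)) { quad <- as_quad(cand); break }
    }
    if (is.null(quad)) {
      abort("could not draw a convex capture quad; reduce corner_jitter_px",
            class = "topotype_domain_error")
    }
    # forward map canonical -> quad; render by inverse mapping
    H <- estimate_homography(quad, frame_corners(n))
    gx <- rep(seq_len(n), each = n); gy <- rep(seq_len(n), times = n)
    sp <- apply_homography(H, cbind(gx, gy))
    out <- array(bilinear_sample(img, sp[, 1], sp[, 2],
                                 fill = .BACKGROUND_RGB[1]),
                 dim = dim(img))
  }

  b <- photometric$brightness %||% 0
  if (b != 0) {
    if (corner_jitter_px == 0) {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(split_seed(rng_seed, "capture"))
    }
    out[] <- pmin(1, pmax(0, out * (1 + runif(1, -b, b))))
  }
  passes <- photometric$blur %||% 0
  if (passes > 0) for (i in seq_len(passes)) out <- box_blur(out)

  list(image = out, true_quad = quad, seed = as.integer(rng_seed))
}

# 3x3 box blur with edge replication, per channel
box_blur <- function(img) {
  d <- dim(img)
  blur1 <- function(m) {
    n1 <- nrow(m); n2 <- ncol(m)
    pad <- m[c(1, 1:n1, n1), c(1, 1:n2, n2)]
    acc <- matrix(0, n1, n2)
    for (di in 0:2) for (dj in 0:2) {
      acc <- acc + pad[di + 1:n1, dj + 1:n2]
    }
    acc / 9
  }
  if (length(d) == 3) {
    for (ch in seq_len(d[3])) img[, , ch] <- blur1(img[, , ch])
    img
  } else blur1(img)
}
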