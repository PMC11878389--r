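#' Absolute diopter color scale for topogram rendering
#'
#' An absolute scale in the style of clinical topographers: equal diopter
#' steps mapped to an ordered palette running from cold (blue, flat) through
#' green (normal central power) and yellow to red (steep). The default spans
#' 35.0-52.0 D in 1.5 D steps (12 colors); the green band contains the
#' default normal central power of 43.5 D.
#'
#' @param k_min,k_max Scale limits in diopters.
#' @param step Bin width in diopters.
#' @return A `color_scale` object: `k_min`, `k_max`, `step`, `colors`
#'   (hex, cold to warm), `hue_deg` (the hue of each bin, degrees).
#' @export
default_color_scale <- function(k_min = 35, k_max = 52, step = 1.5) {
  stopifnot(k_max > k_min, step > 0)
  n <- ceiling((k_max - k_min) / step)
  hue <- 240 * (1 - (seq_len(n) - 1) / (n - 1))  # 240 (blue) -> 0 (red)
  structure(
    list(k_min = k_min, k_max = k_max, step = step,
         colors = grDevices::hsv(hue / 360, 0.85, 0.95),
         hue_deg = hue),
    class = "color_scale"
  )
}

#' Bin powers on a color scale
#'
#' @param k Diopters (vector); `NA` passes through.
#' @param scale A `color_scale`.
#' @return Integer bin indices in `1..length(scale$colors)` (values outside
#'   the span are clipped to the end bins).
#' @export
power_bin <- function(k, scale = default_color_scale()) {
  n <- length(scale$colors)
  pmin(n, pmax(1, floor((k - scale$k_min) / scale$step) + 1L))
}

# overlay / background colors, chosen outside the palette so rendering
# stays invertible to power bins
.OVERLAY_RGB <- c(1, 1, 1)
.BACKGROUND_RGB <- c(0.18, 0.18, 0.18)

#' Render a power map as a color-coded topogram
#'
#' Maps each pixel's power to its color-scale bin and overlays the 3-, 5-
#' and 7-mm zone rings (radii proportional 3:5:7) plus short axis marks at
#' 0/90/180/270 degrees, as printed topograms carry. Deterministic.
#'
#' @param pm A `power_map`.
#' @param scale A `color_scale` spanning the map's clipped range.
#' @param zones_px Radii of the 3/5/7-mm rings in pixels; default derived
#'   from the map scale.
#' @param overlay Draw rings and axis marks (default `TRUE`). Disable for
#'   classifier inputs.
#' @return A `topogram` object: `image` (n x n x 3 array in `[0,1]`),
#'   `zones_px`, `sidecar` (params + scale metadata).
#' @export
render_topogram <- function(pm, scale = default_color_scale(),
                            zones_px = NULL, overlay = TRUE) {
  n <- pm$grid_n
  if (is.null(zones_px)) zones_px <- c(1.5, 2.5, 3.5) / pm$mm_per_px
  bins <- power_bin(pm$values, scale)
  pal <- grDevices::col2rgb(scale$colors) / 255

  img <- array(0, dim = c(n, n, 3))
  inside <- !is.na(bins)
  for (ch in 1:3) {
    plane <- matrix(.BACKGROUND_RGB[ch], n, n)
    plane[inside] <- pal[ch, bins[inside]]
    img[, , ch] <- plane
  }

  if (overlay) {
    g <- grid_polar(n, pm$mm_per_px)
    rpx <- g$r / pm$mm_per_px
    ring <- matrix(FALSE, n, n)
    for (R in zones_px) ring <- ring | abs(rpx - R) < 0.6
    # axis marks just beyond the 7-mm ring
    tick <- rpx > max(zones_px) + 2 & rpx < max(zones_px) + 7 &
      (abs(g$x) < 0.6 * pm$mm_per_px | abs(g$y) < 0.6 * pm$mm_per_px)
    ov <- ring | tick
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[ov] <- .OVERLAY_RGB[ch]
      img[, , ch] <- plane
    }
  }

  structure(
    list(image = img, zones_px = zones_px,
         sidecar = list(params = as.list(pm$params), seed = pm$params$seed,
                        grid_n = n, mm_per_px = pm$mm_per_px,
                        zones_px = zones_px,
                        scale = list(k_min = scale$k_min, k_max = scale$k_max,
                                     step = scale$step))),
    class = "topogram"
  )
}

#' Invert a rendered topogram back to power bins
#'
#' The rendering palette is exactly recoverable: every disc pixel carries
#' one of the scale colors, the overlay is white and the background dark
#' gray. Pixels whose color is not in the palette (overlay, background)
#' return `NA`.
#'
#' @param img An n x n x 3 array in `[0,1]` (or a `topogram`).
#' @param scale The `color_scale` used for rendering.
#' @return Integer matrix of bin indices with `NA` off the color map.
#' @export
invert_topogram <- function(img, scale = default_color_scale()) {
  if (inherits(img, "topogram")) img <- img$image
  pal <- grDevices::col2rgb(scale$colors) / 255
  n <- dim(img)[1]
  # match on quantized 8-bit color keys
  key <- function(r, g, b) {
    paste(round(r * 255), round(g * 255), round(b * 255))
  }
  lut <- setNames(seq_len(ncol(pal)), key(pal[1, ], pal[2, ], pal[3, ]))
  px <- key(img[, , 1], img[, , 2], img[, , 3])
  matrix(unname(lut[px]), n, n)
}

#' @export
print.topogram <- function(x, ...) {
  cat(sprintf("Topogram %dx%d px, %s/%s, zone rings at %.1f/%.1f/%.1f px\n",
              dim(x$image)[1], dim(x$image)[2],
              x$sidecar$params$label, x$sidecar$params$variant,
              x$zones_px[1], x$zones_px[2], x$zones_px[3]))
  invisible(x)
}

#' Plot a topogram with ggplot2
#'
#' @param object A `topogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.topogram <- function(object, ...) {
  img <- object$image
  n <- dim(img)[1]
  df <- tibble(
    x = rep(seq_len(n), each = n),
    y = rep(seq(n, 1), times = n),
    fill = grDevices::rgb(img[, , 1], img[, , 2], img[, , 3])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("%s (%s)", object$sidecar$params$label,
                                  object$sidecar$params$variant))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
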