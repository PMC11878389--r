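#' Examiner-style contour of a power map
#'
#' Automates the examiner's tracing rule so the pipeline can be exercised
#' without a human: for astigmatic and conic patterns the contour is the
#' iso-power level set at half of the smallest active component amplitude
#' above the base power, which traces both semimeridian lobes at one
#' "color shade"; for spherical patterns it is a peripheral ring just
#' inside the 7-mm zone. Level-set polylines are extracted by marching
#' squares on the map grid and returned in canonical-frame millimetres.
#'
#' @param pm A `power_map` built from known parameters.
#' @param label Class label driving the tracing rule; defaults to the
#'   map's own label.
#' @param min_vertices Polylines with fewer vertices are discarded (noise
#'   specks).
#' @return A `contour_set`: list of closed polylines (m x 2 matrices,
#'   columns `x`, `y` in mm) with attributes `level` (diopters, `NA` for
#'   the peripheral ring) and `params`.
#' @export
oracle_contour <- function(pm, label = NULL, min_vertices = 8) {
  p <- as.list(pm$params)
  label <- label %||% p$label

  if (label == "SPHERICAL") {
    r <- 0.95 * 3.5
    th <- seq(0, 2 * pi, length.out = 181)
    ring <- cbind(x = r * cos(th), y = r * sin(th))
    return(new_contour_set(list(ring), level = NA_real_, params = p))
  }

  active <- c(p$amp_sup, p$amp_inf, p$cone_dk)
  active <- active[active > 0]
  scale_step <- 1.5
  if (length(active) == 0 || max(active) < scale_step) {
    abort("pattern amplitude below one color step; nothing to trace",
          class = "topotype_degenerate_error")
  }
  level <- p$k0 + 0.5 * min(active)

  n <- pm$grid_n
  vals <- pm$values
  vals[is.na(vals)] <- p$k0           # flat fill outside the disc
  xs <- ((1:n) - (n + 1) / 2) * pm$mm_per_px
  z <- t(vals[n:1, , drop = FALSE])   # z[i, j] at x = xs[i], y = xs[j]
  cl <- grDevices::contourLines(xs, xs, z, levels = level)
  polys <- purrr::map(cl, function(s) {
    m <- cbind(x = s$x, y = s$y)
    if (nrow(m) >= 2 && any(m[1, ] != m[nrow(m), ])) m <- rbind(m, m[1, ])
    m
  })
  polys <- purrr::keep(polys, ~ nrow(.x) >= min_vertices)
  if (length(polys) == 0) {
    abort("level set empty at the tracing level; degenerate pattern",
          class = "topotype_degenerate_error")
  }
  new_contour_set(polys, level = level, params = p)
}

new_contour_set <- function(polys, level = NA_real_, params = NULL) {
  structure(polys, level = level, params = params,
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("Contour set: %d polyline(s), iso level %s D\n",
              length(x),
              if (is.na(attr(x, "level"))) "- (peripheral ring)"
              else sprintf("%.2f", attr(x, "level"))))
  invisible(x)
}

# polygon area (shoelace, absolute) and centroid of one polyline
poly_area <- function(m) {
  x <- m[, 1]; y <- m[, 2]
  i2 <- c(2:nrow(m), 1)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

# area-weighted polygon centroid (stabler than the vertex mean, whose
# position drifts with marching-squares vertex density)
poly_centroid <- function(m) {
  x <- m[, 1]; y <- m[, 2]
  i2 <- c(2:nrow(m), 1)
  cr <- x * y[i2] - x[i2] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(m[-nrow(m), , drop = FALSE]))
  c(sum((x + x[i2]) * cr) / (6 * a), sum((y + y[i2]) * cr) / (6 * a))
}

# does polygon m contain the point (even-odd rule)?
poly_contains <- function(m, px = 0, py = 0) {
  x <- m[, 1]; y <- m[, 2]
  n <- nrow(m)
  j <- c(n, 1:(n - 1))
  cross <- (y > py) != (y[j] > py)
  xi <- x[j] + (py - y[j]) / (y - y[j]) * (x - x[j])
  sum(cross & xi > px, na.rm = TRUE) %% 2 == 1
}

#' Rasterize a contour set into a binary mask
#'
#' Burns the polyline strokes (and optionally their filled interiors) into
#' an `n` x `n` raster covering the canonical 9 x 9 mm frame. The filled
#' mask is the default classifier input plane.
#'
#' @param contours A `contour_set` (mm coordinates), or an empty list.
#' @param n Raster side in pixels.
#' @param thickness_px Stroke thickness.
#' @param fill Also fill polyline interiors (default `TRUE`).
#' @return An `n` x `n` 0/1 integer matrix.
#' @export
rasterize_contour <- function(contours, n = 64, thickness_px = 1,
                              fill = TRUE) {
  mask <- matrix(0L, n, n)
  if (length(contours) == 0) return(mask)
  mmpp <- 9 / n
  to_px <- function(m) {
    cbind(col = (m[, 1] + 4.5) / mmpp + 0.5,
          row = (4.5 - m[, 2]) / mmpp + 0.5)
  }
  for (poly in contours) {
    px <- to_px(poly)
    if (fill) mask <- mask | fill_polygon(px, n)
    mask <- mask | stroke_polyline(px, n, thickness_px)
  }
  matrix(as.integer(mask), n, n)
}

# even-odd scanline fill of one polygon given in (col,row) pixel coords
fill_polygon <- function(px, n) {
  mask <- matrix(FALSE, n, n)
  xs <- px[, 1]; ys <- px[, 2]
  m <- nrow(px)
  x1 <- xs[-m]; y1 <- ys[-m]; x2 <- xs[-1]; y2 <- ys[-1]
  for (row in seq_len(n)) {
    yc <- row
    hit <- (y1 <= yc & y2 > yc) | (y2 <= yc & y1 > yc)
    if (!any(hit)) next
    xc <- x1[hit] + (yc - y1[hit]) / (y2[hit] - y1[hit]) * (x2[hit] - x1[hit])
    xc <- sort(xc)
    for (k in seq(1, length(xc) - 1, by = 2)) {
      a <- max(1L, ceiling(xc[k])); b <- min(n, floor(xc[k + 1]))
      if (a <= b) mask[row, a:b] <- TRUE
    }
  }
  mask
}

stroke_polyline <- function(px, n, thickness_px) {
  mask <- matrix(FALSE, n, n)
  m <- nrow(px)
  seg_len <- sqrt(rowSums((px[-1, , drop = FALSE] -
                           px[-m, , drop = FALSE])^2))
  pts <- purrr::map(seq_len(m - 1), function(i) {
    k <- max(2, ceiling(seg_len[i] / 0.4))
    t <- seq(0, 1, length.out = k)
    cbind(px[i, 1] + t * (px[i + 1, 1] - px[i, 1]),
          px[i, 2] + t * (px[i + 1, 2] - px[i, 2]))
  })
  pts <- do.call(rbind, pts)
  half <- (thickness_px - 1) / 2
  offs <- expand.grid(dc = -ceiling(half):ceiling(half),
                      dr = -ceiling(half):ceiling(half))
  offs <- offs[offs$dc^2 + offs$dr^2 <= max(half, 0.5)^2 + 1e-9, ,
               drop = FALSE]
  for (k in seq_len(nrow(offs))) {
    cc <- round(pts[, 1]) + offs$dc[k]
    rr <- round(pts[, 2]) + offs$dr[k]
    ok <- cc >= 1 & cc <= n & rr >= 1 & rr <= n
    mask[cbind(rr[ok], cc[ok])] <- TRUE
  }
  mask
}

#' Geometric bow-tie descriptors of a contour set
#'
#' Separates the spherical peripheral ring (a polyline that encloses the
#' map centre at a mean radius beyond the 5-mm zone) from tie lobes, then
#' measures each lobe's maximal radial reach, base width, and direction
#' (the angle of its centroid from the map centre). For two-lobe ties the
#' symmetry ratio is the shorter over the longer reach of the two main
#' lobes, and the perpendicularity angle is the angle between one
#' semimeridian and the perpendicular of the other (90 degrees for a
#' straight bow tie, drifting with skewed radial axes).
#'
#' @param contours A `contour_set`.
#' @return One-row tibble: `lobe_count`, `peripheral`, `lobe_lengths`
#'   (list), `base_widths` (list), `lobe_dirs` (list, degrees),
#'   `steep_axis`, `inter_meridian_angle`, `symmetry_ratio`, `reach_zone`.
#' @export
shape_features <- function(contours) {
  is_ring <- vapply(contours, function(m) {
    poly_contains(m) && min(sqrt(rowSums(m^2))) > 2.0
  }, logical(1))
  lobes <- contours[!is_ring]

  feat <- purrr::map(lobes, function(m) {
    rr <- sqrt(rowSums(m^2))
    ctr <- poly_centroid(m)
    dir <- rad2deg(atan2(ctr[2], ctr[1])) %% 360
    u_perp <- c(-sin(deg2rad(dir)), cos(deg2rad(dir)))
    proj <- m %*% u_perp
    tibble(length = max(rr), width = diff(range(proj)),
           dir = dir, area = poly_area(m))
  })
  feat <- if (length(feat)) dplyr::bind_rows(feat) else
    tibble(length = numeric(), width = numeric(), dir = numeric(),
           area = numeric())
  feat <- dplyr::arrange(feat, dplyr::desc(.data$length))

  n_lobes <- nrow(feat)
  if (n_lobes >= 2) {
    ang <- ang_diff(feat$dir[1], feat$dir[2])
    perp <- ang - 90
    sym <- feat$length[2] / feat$length[1]
  } else {
    perp <- NA_real_
    sym <- NA_real_
  }
  reach <- if (n_lobes == 0) NA_character_ else {
    mx <- max(feat$length)
    if (mx <= 1.5) "3" else if (mx <= 2.5) "5" else "7"
  }
  tibble(
    lobe_count = n_lobes,
    peripheral = any(is_ring),
    lobe_lengths = list(feat$length),
    base_widths = list(feat$width),
    lobe_dirs = list(feat$dir),
    steep_axis = if (n_lobes > 0) feat$dir[1] %% 180 else NA_real_,
    inter_meridian_angle = perp,
    symmetry_ratio = sym,
    reach_zone = reach
  )
}

#' Default thresholds for the rule-based reference classifier
#'
#' @return Named list: `symmetry` (minimum symmetry ratio for the
#'   symmetric class), `perp_tol` (tolerated deviation of the
#'   perpendicularity angle from 90 degrees), `ratio_floor` (below this the
#'   weaker half is deemed rudimentary, i.e. irregular).
#' @export
default_rule_thresholds <- function() {
  list(symmetry = 0.75, perp_tol = 15, ratio_floor = 0.40)
}

#' Rule-based classification from shape features
#'
#' A transparent decision list mirroring the clinical taxonomy, used as the
#' reference labeller for synthetic data (and as a sanity anchor for the
#' neural classifier):
#'
#' 1. no tie lobes (peripheral ring only) -> `SPHERICAL`;
#' 2. a single lobe, or more than two -> `IRREGULAR` (no pair of
#'    well-defined semimeridians);
#' 3. perpendicularity angle off 90 degrees by more than `perp_tol` ->
#'    `IRREGULAR` (skewed radial axes);
#' 4. symmetry ratio below `ratio_floor` -> `IRREGULAR` (rudimentary
#'    half-tie);
#' 5. symmetry ratio at or above `symmetry` -> `SYMMETRIC` (a ratio exactly
#'    at the threshold breaks toward the less severe class);
#' 6. otherwise -> `ASYMMETRIC`.
#'
#' @param features One-row tibble from [shape_features()].
#' @param thresholds See [default_rule_thresholds()].
#' @return A class label string.
#' @export
rule_classify <- function(features, thresholds = default_rule_thresholds()) {
  f <- features
  if (f$lobe_count == 0) return("SPHERICAL")
  if (f$lobe_count != 2) return("IRREGULAR")
  if (abs(f$inter_meridian_angle - 90) > thresholds$perp_tol) return("IRREGULAR")
  if (f$symmetry_ratio < thresholds$ratio_floor) return("IRREGULAR")
  if (f$symmetry_ratio >= thresholds$symmetry) return("SYMMETRIC")
  "ASYMMETRIC"
}

#' Read / write contour sets as JSON
#'
#' Contours interchange as a JSON list of polylines in mm coordinates, the
#' format used for manually traced contours of real captures.
#'
#' @param contours A `contour_set`.
#' @param path File path.
#' @return `read_contour` returns a `contour_set`; `write_contour` returns
#'   `path` invisibly.
#' @export
write_contour <- function(contours, path) {
  payload <- list(
    level = attr(contours, "level"),
    polylines = purrr::map(contours, ~ list(x = .x[, 1], y = .x[, 2]))
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_contour
#' @export
read_contour <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  polys <- purrr::map(seq_len(nrow_or_len(payload$polylines)), function(i) {
    pl <- if (is.data.frame(payload$polylines)) {
      list(x = payload$polylines$x[[i]], y = payload$polylines$y[[i]])
    } else payload$polylines[[i]]
    cbind(x = as.numeric(pl$x), y = as.numeric(pl$y))
  })
  new_contour_set(polys, level = payload$level %||% NA_real_)
}

nrow_or_len <- function(x) {
  if (is.data.frame(x) || is.matrix(x)) nrow(x) else length(x)
}
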