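#' Evaluate the axial-power surface model at polar coordinates
#'
#' The simulator's quantitative surface model. Axial power in diopters at
#' radius `r` (mm from the corneal apex) and direction `theta` (degrees,
#' counterclockwise from the rightward horizontal; the superior semifield is
#' `0 < theta < 180`):
#'
#' \deqn{K(r,\theta) = k_0 + \Delta K_c e^{-r^2/2\sigma_c^2}
#'   + A(\theta)\cos^2(\theta - \phi_{\mathrm{eff}}(\theta))\, w(r; E(\theta))
#'   + \Delta K_{cone} G(r,\theta) + \eta(x, y)}
#'
#' where the astigmatic amplitude `A`, radial extent `E` and effective steep
#' axis take the superior or inferior value according to which semimeridian
#' of the steep axis the point is closer to; `w` is a logistic radial window
#' falling off at the extent; the cone term `G` is an anisotropic Gaussian
#' centred at `(cone_r, cone_theta)` with radial width `cone_sigma` and
#' tangential (arc) width `cone_sigma_t`; the central term models
#' post-refractive-surgery flattening/steepening; and `eta` is a smooth,
#' seeded band-limited noise field with pointwise standard deviation
#' `noise_sd`. Skew (`skew_deg`) rotates the inferior semimeridian's
#' effective axis, producing the loss of perpendicularity between the two
#' bow-tie halves seen in one keratoconus variant.
#'
#' @param params A `surface_params` row from [sample_params()].
#' @param r,theta Numeric vectors (recycled): radius in mm, `0 <= r <= 4.5`,
#'   and direction in degrees.
#' @return Axial power in diopters, same length as the longer of `r`,
#'   `theta`.
#' @export
#' @examples
#' p <- sample_params("SPHERICAL", "NONE", rng_seed = 7)
#' eval_power(p, 2, 45) - p$k0   # 0 apart from the smooth noise field
eval_power <- function(params, r, theta) {
  if (any(r < 0 | r > 4.5)) {
    abort("radius out of the 4.5-mm corneal disc", class = "topotype_domain_error")
  }
  n <- max(length(r), length(theta))
  r <- rep_len(r, n); theta <- rep_len(theta, n) %% 360
  p <- as.list(params)

  k <- rep(p$k0, n)

  if (p$central_dk != 0) {
    k <- k + p$central_dk * exp(-r^2 / (2 * p$central_sigma^2))
  }

  if (p$amp_sup > 0 || p$amp_inf > 0) {
    d_sup <- p$axis_phi            # superior semimeridian direction
    is_sup <- ang_diff(theta, d_sup) <= 90
    amp <- ifelse(is_sup, p$amp_sup, p$amp_inf)
    ext <- ifelse(is_sup, p$radial_extent_sup, p$radial_extent_inf)
    phi_eff <- ifelse(is_sup, p$axis_phi, p$axis_phi + p$skew_deg)
    # radial window: logistic fall-off at the lobe extent, with a central
    # pinch (the apex stays near-spherical, so the two halves of the tie
    # are distinct lobes rather than one band through the centre)
    w <- stats::plogis((ext - r) / 0.3) * stats::plogis((r - 0.5) / 0.15)
    k <- k + amp * cos(deg2rad(theta - phi_eff))^2 * w * (amp > 0 & ext > 0)
  }

  if (p$cone_dk > 0) {
    dr <- r - p$cone_r
    arc <- p$cone_r * deg2rad(ang_diff(theta, p$cone_theta))
    k <- k + p$cone_dk *
      exp(-(dr^2 / (2 * p$cone_sigma^2) + arc^2 / (2 * p$cone_sigma_t^2)))
  }

  if (p$noise_sd > 0) {
    x <- r * cos(deg2rad(theta)); y <- r * sin(deg2rad(theta))
    k <- k + p$noise_sd * noise_field(p$seed, x, y)
  }
  k
}

# Smooth band-limited noise: a fixed sum of seeded random plane waves,
# normalised to unit pointwise variance. Deterministic at any coordinate,
# so maps of the same surface at different grid resolutions agree.
noise_field <- function(seed, x, y) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(split_seed(seed, "noise"))
  m <- 6L
  freq <- runif(m, 0.8, 2.5)           # cycles-ish per mm (rad/mm)
  dir <- runif(m, 0, 2 * pi)
  phase <- runif(m, 0, 2 * pi)
  amp <- rnorm(m)
  out <- 0
  for (j in seq_len(m)) {
    out <- out + amp[j] *
      cos(freq[j] * (cos(dir[j]) * x + sin(dir[j]) * y) + phase[j])
  }
  out / sqrt(sum(amp^2) / 2)
}

#' Sample the surface model on a centred Cartesian grid
#'
#' Builds the ground-truth power map: a `grid_n` x `grid_n` matrix of
#' diopters over the 4.5-mm-radius corneal disc, `NA` outside the disc.
#' Row 1 is the superior (image-top) edge.
#'
#' @param params A `surface_params` row.
#' @param grid_n Grid side in pixels (>= 64).
#' @param mm_per_px Physical scale; default fits the 9-mm disc to the grid.
#' @return A `power_map` object (list: `values`, `grid_n`, `mm_per_px`,
#'   `params`).
#' @export
make_power_map <- function(params, grid_n = 256, mm_per_px = 9 / grid_n) {
  if (grid_n < 64) abort("grid_n must be >= 64", class = "topotype_config_error")
  ctr <- (grid_n + 1) / 2
  xs <- ((1:grid_n) - ctr) * mm_per_px
  x <- matrix(xs, grid_n, grid_n, byrow = TRUE)
  y <- matrix(rev(xs), grid_n, grid_n)   # +y is up (superior)
  r <- sqrt(x^2 + y^2)
  theta <- (rad2deg(atan2(y, x))) %% 360
  inside <- r <= 4.5
  vals <- matrix(NA_real_, grid_n, grid_n)
  vals[inside] <- eval_power(params, r[inside], theta[inside])
  structure(
    list(values = vals, grid_n = as.integer(grid_n), mm_per_px = mm_per_px,
         params = params),
    class = "power_map"
  )
}

#' @export
print.power_map <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("Power map %dx%d px (%.4f mm/px), %s/%s, %.1f-%.1f D\n",
              x$grid_n, x$grid_n, x$mm_per_px,
              x$params$label, x$params$variant, rng[1], rng[2]))
  invisible(x)
}

# polar coordinates (r mm, theta deg) of every pixel of an n-grid
grid_polar <- function(grid_n, mm_per_px) {
  ctr <- (grid_n + 1) / 2
  xs <- ((1:grid_n) - ctr) * mm_per_px
  x <- matrix(xs, grid_n, grid_n, byrow = TRUE)
  y <- matrix(rev(xs), grid_n, grid_n)
  list(x = x, y = y, r = sqrt(x^2 + y^2),
       theta = (rad2deg(atan2(y, x))) %% 360)
}
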