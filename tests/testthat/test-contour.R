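nl_map <- function(lab, variant = NULL, seed = 1, grid_n = 96) {
  make_power_map(sample_params(lab, variant, policy = noiseless_policy(),
                               rng_seed = seed), grid_n = grid_n)
}

test_that("the spherical contour is a near-perfect peripheral circle", {
  cs <- oracle_contour(nl_map("SPHERICAL"))
  expect_length(cs, 1)
  m <- cs[[1]]
  A <- topotype:::poly_area(m)
  P <- sum(sqrt(rowSums(diff(m)^2)))
  expect_gt(4 * pi * A / P^2, 0.99)
  expect_equal(max(sqrt(rowSums(m^2))), 0.95 * 3.5, tolerance = 1e-6)
})

test_that("symmetric ties give two mirror-symmetric lobes", {
  for (s in c(1, 4, 9)) {
    pm <- nl_map("SYMMETRIC", seed = s)
    cs <- oracle_contour(pm)
    expect_length(cs, 2)
    phi <- pm$params$axis_phi
    # reflect lobe 1 across the steep axis: should overlay one of the lobes
    th <- deg2rad_t(phi)
    Rm <- matrix(c(cos(2 * th), sin(2 * th), sin(2 * th), -cos(2 * th)), 2, 2)
    refl <- cs[[1]] %*% Rm
    d1 <- hausdorff(refl, cs[[1]])
    d2 <- hausdorff(refl, cs[[2]])
    expect_lt(min(d1, d2), 0.25)   # mm
  }
})

test_that("a classic inferior cone traces one lobe in the lower half", {
  cs <- oracle_contour(nl_map("IRREGULAR", "CLASSIC_INFERIOR", seed = 3))
  expect_length(cs, 1)
  ctr <- topotype:::poly_centroid(cs[[1]])
  expect_lt(ctr[2], 0)
})

test_that("patterns below one color step are degenerate", {
  p <- sample_params("SYMMETRIC", policy = noiseless_policy(), rng_seed = 1)
  p$amp_sup <- p$amp_inf <- 1.0   # below the 1.5 D step
  pm <- make_power_map(p, grid_n = 96)
  expect_error(oracle_contour(pm), class = "topotype_degenerate_error")
})

test_that("rasterization covers the analytic circle area and strokes scale", {
  th <- seq(0, 2 * pi, length.out = 200)
  circle <- new_contour_set_t(list(cbind(2 * cos(th), 2 * sin(th))))
  for (n in c(64, 128)) {
    filled <- rasterize_contour(circle, n = n, fill = TRUE)
    frac <- sum(filled) / n^2
    # the 1-px boundary stroke widens the disc by about half a pixel
    r_eff <- 2 + 0.75 * 9 / n
    expect_lt(abs(frac - pi * r_eff^2 / 81) / (pi * r_eff^2 / 81), 0.05)
  }
  s64 <- sum(rasterize_contour(circle, n = 64, fill = FALSE))
  s128 <- sum(rasterize_contour(circle, n = 128, fill = FALSE))
  expect_lt(abs(s128 / s64 - 2), 0.25)
  expect_equal(rasterize_contour(new_contour_set_t(list()), n = 32),
               matrix(0L, 32, 32))
})

test_that("a rasterized contour traces back close to the original", {
  pm <- nl_map("SYMMETRIC", seed = 6, grid_n = 128)
  cs <- oracle_contour(pm)
  n <- 128
  mask <- rasterize_contour(cs, n = n, fill = TRUE)
  # independent trace of the mask boundary
  xs <- ((1:n) - (n + 1) / 2) * (9 / n)
  z <- t(mask[n:1, ])
  back <- grDevices::contourLines(xs, xs, z, levels = 0.5)
  expect_gte(length(back), 1)
  all_back <- do.call(rbind, lapply(back, function(s) cbind(s$x, s$y)))
  all_orig <- do.call(rbind, cs)
  expect_lt(hausdorff(all_back, all_orig), 2.5 * 9 / n)
})

test_that("shape features recover generator geometry", {
  f_sym <- shape_features(oracle_contour(nl_map("SYMMETRIC", seed = 2)))
  expect_equal(f_sym$lobe_count, 2)
  expect_gt(f_sym$symmetry_ratio, 0.9)
  expect_lt(abs(f_sym$inter_meridian_angle - 90), 10)

  pm <- nl_map("ASYMMETRIC", seed = 3)
  f_asym <- shape_features(oracle_contour(pm))
  ext_ratio <- min(pm$params$radial_extent_sup, pm$params$radial_extent_inf) /
    max(pm$params$radial_extent_sup, pm$params$radial_extent_inf)
  expect_equal(f_asym$symmetry_ratio, ext_ratio, tolerance = 0.25)
  expect_lt(f_asym$symmetry_ratio, 0.75)

  f_one <- shape_features(oracle_contour(nl_map("IRREGULAR",
                                                "CLASSIC_INFERIOR")))
  expect_equal(f_one$lobe_count, 1)
})

test_that("the steep axis follows the generated axis", {
  for (s in c(2, 5, 8)) {
    pm <- nl_map("SYMMETRIC", seed = s)
    f <- shape_features(oracle_contour(pm))
    d <- abs(f$steep_axis - pm$params$axis_phi)
    expect_lt(min(d, 180 - d), 8)
  }
})

test_that("symmetry features are invariant to whole-map rotation", {
  p0 <- sample_params("ASYMMETRIC", policy = noiseless_policy(), rng_seed = 5)
  f0 <- shape_features(oracle_contour(make_power_map(p0, grid_n = 96)))
  p1 <- p0
  p1$axis_phi <- (p0$axis_phi + 40) %% 180
  f1 <- shape_features(oracle_contour(make_power_map(p1, grid_n = 96)))
  expect_equal(f0$symmetry_ratio, f1$symmetry_ratio, tolerance = 0.06)
  expect_equal(f0$inter_meridian_angle, f1$inter_meridian_angle,
               tolerance = 6)
})

test_that("the rule classifier reproduces noiseless labels and tie-breaks", {
  pol <- noiseless_policy()
  for (lab in CLASS_LABELS) {
    for (s in 1:40) {
      pm <- make_power_map(sample_params(lab, policy = pol, rng_seed = s),
                           grid_n = 96)
      got <- rule_classify(shape_features(oracle_contour(pm)))
      expect_identical(got, lab)
    }
  }
  # a ratio exactly at the threshold counts as symmetric
  f <- tibble::tibble(lobe_count = 2, inter_meridian_angle = 90,
                      symmetry_ratio = default_rule_thresholds()$symmetry)
  expect_identical(rule_classify(f), "SYMMETRIC")
})

test_that("rudimentary half-ties are flagged irregular", {
  for (s in 1:25) {
    pm <- nl_map("IRREGULAR", "RUDIMENTARY_TIE", seed = s)
    f <- shape_features(oracle_contour(pm))
    expect_identical(rule_classify(f), "IRREGULAR")
    if (f$lobe_count == 2) {
      expect_lt(f$symmetry_ratio, default_rule_thresholds()$ratio_floor)
    }
  }
})

test_that("contours round-trip through their JSON interchange format", {
  cs <- oracle_contour(nl_map("SYMMETRIC", seed = 7))
  path <- tempfile(fileext = ".json")
  write_contour(cs, path)
  back <- read_contour(path)
  expect_length(back, length(cs))
  for (i in seq_along(cs)) {
    expect_equal(unname(back[[i]]), unname(cs[[i]]), tolerance = 1e-12)
  }
  expect_equal(attr(back, "level"), attr(cs, "level"))
  unlink(path)
})
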