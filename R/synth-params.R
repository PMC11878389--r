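#' Pattern variants recognised by the simulator
#'
#' `NONE` applies to all classes. `POST_MYOPIC` and `POST_HYPEROPIC` are
#' spherical-pattern differential diagnoses (surfaces after laser refractive
#' surgery, with a centrally flattened or steepened zone). The remaining five
#' are the classic morphologies of irregular astigmatism: the classic
#' inferior cone, skewed radial axes (loss of perpendicularity between the
#' two semimeridians), pellucid marginal degeneration (a wide inferior
#' arcuate band of steepening), an incomplete bow tie (one half absent),
#' and inferior steepening with a rudimentary superior half.
#'
#' @format Named list mapping each class label to its admissible variants.
#' @export
CLASS_VARIANTS <- list(
  SPHERICAL = c("NONE", "POST_MYOPIC", "POST_HYPEROPIC"),
  SYMMETRIC = "NONE",
  ASYMMETRIC = "NONE",
  IRREGULAR = c("CLASSIC_INFERIOR", "SKEWED", "PELLUCID",
                "INCOMPLETE_TIE", "RUDIMENTARY_TIE")
)

#' Default variant-sampling policy
#'
#' Probabilities used by [sample_params()] when drawing a variant for a
#' class, plus the knobs that keep the synthetic labels well-posed: the
#' minimum relative lobe difference that defines asymmetry, the minimum
#' inter-semimeridian skew that defines the skewed irregular variant, and
#' the fraction of inferior cone placements (keratoconus steepening is
#' "usually inferior").
#'
#' @return A named list of policy settings.
#' @export
default_variant_policy <- function() {
  list(
    spherical_probs = c(NONE = 0.70, POST_MYOPIC = 0.15, POST_HYPEROPIC = 0.15),
    irregular_probs = c(CLASSIC_INFERIOR = 0.40, SKEWED = 0.15, PELLUCID = 0.15,
                        INCOMPLETE_TIE = 0.15, RUDIMENTARY_TIE = 0.15),
    min_asymmetry = 0.25,    # relative lobe difference defining ASYMMETRIC
    min_skew_deg = 20,       # skew below this does not qualify as irregular
    inferior_fraction = 0.85, # P(cone in the inferior half-plane)
    noise_sd = 0.15          # diopters, smooth surface noise
  )
}

# axis of the steep meridian: mixture of with-the-rule (near 90 deg),
# against-the-rule (near 0/180 deg) and oblique, folded into [0, 180)
sample_axis <- function() {
  u <- runif(1)
  phi <- if (u < 0.45) {
    rnorm(1, 90, 12)
  } else if (u < 0.80) {
    rnorm(1, 0, 12)
  } else {
    runif(1, 0, 180)
  }
  phi %% 180
}

#' Sample surface parameters for one synthetic topogram
#'
#' Draws the parameters of the quantitative axial-power surface model for a
#' requested diagnostic class (and optionally a specific variant), such that
#' the class invariants hold by construction:
#'
#' * `SPHERICAL`: no astigmatic amplitude, no cone (post-surgical variants
#'   add a central power offset only);
#' * `SYMMETRIC`: equal semimeridian amplitudes and radial extents;
#' * `ASYMMETRIC`: both bow-tie halves present but with a relative extent
#'   difference of at least `min_asymmetry`;
#' * `IRREGULAR`: a focal cone (`cone_dk > 0`) and/or loss of
#'   perpendicularity (`skew_deg >= min_skew_deg`), per variant.
#'
#' The same `(label, variant, rng_seed)` always returns identical
#' parameters.
#'
#' @param label One of [CLASS_LABELS].
#' @param variant A variant admissible for `label`, or `NULL` to draw one
#'   from the policy probabilities.
#' @param policy A policy list, see [default_variant_policy()].
#' @param rng_seed Non-negative integer seed.
#' @return A one-row tibble of surface parameters (class `surface_params`).
#' @export
#' @examples
#' sample_params("SYMMETRIC", rng_seed = 1)
sample_params <- function(label, variant = NULL,
                          policy = default_variant_policy(),
                          rng_seed = 0) {
  label <- as.character(as_class_label(label))
  admissible <- CLASS_VARIANTS[[label]]
  if (!is.null(variant) && !variant %in% admissible) {
    abort(sprintf("variant '%s' is not valid for class %s", variant, label),
          class = "topotype_config_error")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(split_seed(rng_seed, "params", label))

  if (is.null(variant)) {
    variant <- switch(label,
      SPHERICAL = sample(names(policy$spherical_probs), 1,
                         prob = policy$spherical_probs),
      IRREGULAR = sample(names(policy$irregular_probs), 1,
                         prob = policy$irregular_probs),
      "NONE"
    )
  }

  p <- list(
    label = label, variant = variant,
    k0 = min(45, max(42, rnorm(1, 43.5, 0.75))),
    amp_sup = 0, amp_inf = 0, axis_phi = sample_axis(),
    radial_extent_sup = 0, radial_extent_inf = 0,
    cone_dk = 0, cone_r = 0, cone_theta = 0,
    cone_sigma = 1, cone_sigma_t = 1,
    central_dk = 0, central_sigma = 1.5,
    skew_deg = 0, noise_sd = policy$noise_sd,
    seed = as.integer(rng_seed)
  )

  if (label == "SPHERICAL") {
    if (variant == "POST_MYOPIC") p$central_dk <- -runif(1, 2, 4)
    if (variant == "POST_HYPEROPIC") p$central_dk <- runif(1, 2, 4)
  } else if (label == "SYMMETRIC") {
    amp <- runif(1, 2.5, 5.0)
    ext <- runif(1, 2.3, 3.2)
    p$amp_sup <- p$amp_inf <- amp
    p$radial_extent_sup <- p$radial_extent_inf <- ext
  } else if (label == "ASYMMETRIC") {
    amp <- runif(1, 2.5, 5.0)
    ext_big <- runif(1, 2.7, 3.2)
    ext_small <- ext_big * runif(1, 0.50, 0.62)
    p$amp_sup <- p$amp_inf <- amp
    if (runif(1) < 0.5) {   # which half is the smaller one
      p$radial_extent_sup <- ext_small
      p$radial_extent_inf <- ext_big
    } else {
      p$radial_extent_sup <- ext_big
      p$radial_extent_inf <- ext_small
    }
  } else {
    p <- sample_irregular(p, variant, policy)
  }
  structure(as_tibble(p[!vapply(p, is.null, logical(1))]),
            class = c("surface_params", class(tibble())))
}

# cone placement angle: predominantly inferior (image-bottom) half-plane
sample_cone_theta <- function(inferior_fraction) {
  if (runif(1) < inferior_fraction) {
    min(350, max(190, rnorm(1, 270, 25)))
  } else {
    runif(1, 10, 170)
  }
}

sample_irregular <- function(p, variant, policy) {
  if (variant == "CLASSIC_INFERIOR") {
    p$cone_dk <- runif(1, 6, 12)
    p$cone_r <- runif(1, 1.2, 1.8)
    p$cone_theta <- sample_cone_theta(policy$inferior_fraction)
    p$cone_sigma <- runif(1, 0.8, 1.2)
    p$cone_sigma_t <- p$cone_sigma
  } else if (variant == "SKEWED") {
    amp <- runif(1, 2.5, 4.5)
    ext <- runif(1, 2.4, 3.2)
    p$amp_sup <- amp
    p$amp_inf <- amp * runif(1, 0.88, 1.0)
    p$radial_extent_sup <- ext
    p$radial_extent_inf <- ext * runif(1, 0.88, 1.0)
    p$skew_deg <- sample(c(-1, 1), 1) * runif(1, max(22, policy$min_skew_deg), 40)
  } else if (variant == "PELLUCID") {
    p$cone_dk <- runif(1, 5, 9)
    p$cone_r <- runif(1, 2.5, 2.9)
    p$cone_theta <- min(320, max(220, rnorm(1, 270, 15)))
    p$cone_sigma <- runif(1, 0.35, 0.5)
    p$cone_sigma_t <- runif(1, 2.0, 3.0)  # wide arcuate band
  } else if (variant == "INCOMPLETE_TIE") {
    amp <- runif(1, 3.0, 4.5)
    ext <- runif(1, 2.0, 2.6)
    inferior <- runif(1) < 0.8
    if (inferior) {
      p$amp_inf <- amp; p$radial_extent_inf <- ext
    } else {
      p$amp_sup <- amp; p$radial_extent_sup <- ext
    }
    # focal steepening embedded in the surviving half
    d_sup <- p$axis_phi
    lobe_dir <- if (inferior) (d_sup + 180) %% 360 else d_sup
    p$cone_dk <- runif(1, 3, 4)
    p$cone_r <- runif(1, 1.2, 1.6)
    p$cone_theta <- lobe_dir
    p$cone_sigma <- runif(1, 0.8, 1.1)
    p$cone_sigma_t <- p$cone_sigma
  } else if (variant == "RUDIMENTARY_TIE") {
    # large inferior cone with a short, faint superior half-tie
    p$amp_sup <- runif(1, 1.6, 2.0)
    p$radial_extent_sup <- runif(1, 0.70, 0.95)
    p$cone_dk <- runif(1, 6.5, 7.5)
    p$cone_r <- runif(1, 1.3, 1.6)
    p$cone_theta <- min(340, max(200, rnorm(1, 270, 20)))
    p$cone_sigma <- runif(1, 0.75, 0.85)
    p$cone_sigma_t <- p$cone_sigma
  } else {
    abort(sprintf("unknown irregular variant '%s'", variant),
          class = "topotype_config_error")
  }
  p
}

# save/restore the global RNG state so seeded draws inside the package do
# not disturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}
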