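---
title: "Methods: simulating and classifying corneal topography patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying corneal topography patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Color-coded corneal topograms summarise the axial refractive power of the
anterior cornea. Clinicians read them as one of four basic patterns:
a **spherical** cornea (uniform central color), **regular symmetric
astigmatism** (a bow tie of two similar semimeridian lobes along the steep
meridian), **regular asymmetric astigmatism** (a bow tie whose halves differ
in length and/or width), and **irregular astigmatism / keratoconus** (no
pair of well-defined meridians — classically a focal inferior steepening,
but also skewed radial axes, pellucid marginal degeneration, an incomplete
bow tie, or a rudimentary superior half-tie). Irregular astigmatism is the
screening-positive finding: it contraindicates laser refractive surgery and
changes follow-up.

`topotype` re-implements, as an auditable research pipeline, a
semi-automatic screening workflow in which a printed topogram is
photographed, rectified into a canonical frame whose 3/5/7-mm reference
zones coincide with the printout's, contoured examiner-style, and
classified by a small convolutional network. The clinical image bank such
systems are trained on is private, so the package ships a parametric
simulator whose labelled output stands in for it, plus the fixed published
confusion counts of the original 212-image evaluation as a reference
fixture (`reference_confusion()`).

## The surface model

No quantitative surface model is standard for this taxonomy; ours is the
minimal construction that produces the four morphologies. Axial power in
diopters at polar position $(r, \theta)$ (mm, degrees; superior field is
$0<\theta<180$):

$$
K(r,\theta) = k_0
  + \Delta K_c\, e^{-r^2/2\sigma_c^2}
  + A(\theta)\cos^2\!\big(\theta-\phi_{\text{eff}}(\theta)\big)\, w(r)
  + \Delta K_{\text{cone}}\, G(r,\theta)
  + \eta(x,y)
$$

* $k_0$: base power, drawn near 43.5 D (normal central cornea, the green
  band of the color scale).
* $A$, radial extent $E$, and the effective steep axis take the superior
  or inferior value according to which semimeridian the point is nearer;
  equal values give the symmetric bow tie, unequal extents the asymmetric
  one.
* $w(r) = \operatorname{logistic}\!\big((E-r)/0.3\big)\cdot
  \operatorname{logistic}\!\big((r-0.5)/0.15\big)$: the tie falls off at
  its extent and is pinched at the apex (the apex stays near-spherical),
  so the two halves of the tie are distinct closed lobes, as they are in
  traced contours.
* $\phi_{\text{eff}}$ adds `skew_deg` to the inferior semimeridian only —
  the "loss of perpendicularity" variant.
* $G$ is an anisotropic Gaussian cone at $(r_c, \theta_c)$ with radial
  width $\sigma_r$ and tangential (arc) width $\sigma_t$; $\sigma_t \gg
  \sigma_r$ yields the arcuate inferior band of pellucid marginal
  degeneration.
* $\Delta K_c$ models post-refractive-surgery central flattening (myopic
  ablation, colder central colors) or steepening (hyperopic, warmer);
  these attach only to the spherical class, as its differential diagnoses.
* $\eta$ is a smooth seeded band-limited noise field (a fixed sum of six
  random plane waves, unit pointwise variance, scaled by `noise_sd`,
  default 0.15 D). Because it is parametric, the same surface evaluates
  identically on any grid.

Variant parameter windows (amplitudes 2.5–5 D, extents 2–3.4 mm, cone
peaks 3–12 D, skew 22–40°) were chosen once so that (a) values are
clinically plausible, (b) every traced contour stays within the 7-mm zone,
and (c) the four classes are well separated in contour geometry, so every
synthetic label is well-posed. The asymmetric
class uses an extent ratio of 0.50–0.62 between the halves (at least a 25%
relative difference); the rudimentary-tie variant uses a superior extent
no larger than 0.95 mm against a cone reach of at least ~2.5 mm.

## Color scale and rendering

Topographers print absolute scales with fixed diopter steps. We adopt
35.0–52.0 D in 1.5 D steps: 12 colors from blue (flat) through green
(normal) and yellow to red (steep), with 43.5 D in the green band. Each
pixel's color is exactly the palette entry of its power bin, the zone
rings (radii proportional 3:5:7) and axis marks are drawn in white, and
the background is a dark gray outside the palette — so rendering is
exactly invertible to power bins off the overlay, which the tests exploit
as a lookup-table oracle.

## Capture and rectification

`distort_capture()` jitters the four frame corners (default up to 12 px on
a 256-px frame), warps the render through the induced projective
transform, and optionally adds brightness change and box blur; the
jittered quad is returned as ground truth. `estimate_homography()` is the
standard exact four-point direct linear estimate (an 8×8 linear solve with
$h_{33}=1$); corners are canonicalised by angular sort around their
centroid so user click-order is forgiving. `warp_to_canonical()` inverse-
maps with bilinear interpolation. Captured RGB converts to HSV with the
standard hexcone transform; hue isolates the color band from lighting, and
`zone_alignment_error()` measures the mean radial distance of detected
ring pixels from the canonical 3/5/7-mm radii as a recapture quality gate.

## The examiner oracle and the rule classifier

The deployed workflow has a human trace the tie "following the same color
shade in the two semimeridians"; for a testable pipeline we automate that
examiner. For tie/cone patterns the contour is the iso-power level set at
$k_0 + \tfrac12\min(\text{active amplitudes})$ — half the *smallest*
active component, so both semimeridian lobes are traced at one shade even
when the halves differ. For spherical patterns it is a peripheral ring at
95% of the 7-mm zone radius. Patterns whose largest amplitude is below one
color step (1.5 D) are degenerate and raise an error. A manual-contour
path (JSON polylines in mm) is kept for real images.

From the contour, `shape_features()` measures per-lobe maximal radial
reach, base width, and direction (area centroid angle); the symmetry ratio
(shorter over longer reach of the two main lobes); and a perpendicularity
angle — the angle between one semimeridian and the perpendicular of the
other, 90° for a straight bow tie, drifting by the skew for skewed radial
axes. This convention makes "approximately 90°" the normal reading and
deviation beyond ±15° the irregularity criterion.

`rule_classify()` is a transparent decision list: no lobes → spherical;
one lobe (or more than two) → irregular; perpendicularity off by more than
15° → irregular; symmetry ratio below 0.40 → irregular (rudimentary half);
at or above 0.75 → symmetric (ties break toward the less severe class);
otherwise asymmetric. The thresholds were fixed together with the
generator windows so that noiseless synthetic data classify perfectly;
this rule-based reference anchors dataset label quality independently of
the network (at the default noise the agreement stays above 99%).

## The network

The architecture is one or more convolution/max-pooling pairs, then a
dense ReLU layer and a 4-way softmax. The default —

```{r}
cnn_spec(input_size = 32, channels = 2,
         blocks = list(c(5, 8), c(3, 16)), dense_units = 64)
```

— takes a 32×32 two-plane input (filled contour mask + normalised hue) and
is the smallest configuration we found that separates the synthetic
classes in minutes on one CPU core; at 64×64 the same architecture learns
equally well but costs about four times the arithmetic for no measurable
accuracy gain on these inputs. Training is plain minibatch SGD (batch 32,
rate 0.01) on the cross-entropy, with augmentation restricted to small
rotations (±10°, nearest-neighbour) — never vertical flips, because the
superior/inferior distinction is diagnostic. "Training seasons" are
epochs; the per-epoch held-out accuracy curve is first-class output
(`train_cnn()$curve`, plotted by `autoplot()`). Every stochastic choice
(weights, shuffling, augmentation) derives from one integer seed through a
counter-based hash (`split_seed()`), so runs are bit-reproducible on one
thread and module order cannot change any stream.

Convolution and pooling inner loops are compiled (Rcpp): patch extraction
as `im2col` feeding BLAS matrix products, with the exact adjoint for the
backward pass (verified against finite differences in the tests).

## Evaluation

`confusion_matrix()` uses rows = truth, columns = prediction, in the fixed
order spherical / symmetric / asymmetric / irregular. All percentages are
rounded half-up to 2 decimals, matching the published reporting style.
Screening metrics collapse the 4×4 table against the irregular class:
sensitivity (and its complement, the false-negative rate) on the positive
row, specificity (and false positives) on the rest.
`reference_confusion()` returns the published 212-image evaluation counts
reconstructed from the per-class success figures and the stated identity
of each error; the published spherical-row percentage (97.15%) is
arithmetically inconsistent with its own counts (34/35 = 97.14%) and we
deliberately reproduce the counts, not the typo.

## Problem sizes and what the tests show

The default bank emulates the original composition — 275 spherical, 302
symmetric, 295 asymmetric, 300 irregular; 240 per class train (960,
81.91%) and 212 test (18.09%). Contours are traced on 96-px power maps and
rasterized to the 32-px classifier input; rendered topograms default to
256 px and the end-to-end capture stage to 128 px. The training-curve
benchmark trains the default network for 100 epochs at three seeds on the
full 960/212 bank; typical mean per-epoch held-out accuracy is 97–98%,
comfortably above the 90% average the original system reported on its own
curve. The acceptance script (`scripts/acceptance.R`) recomputes exactly
that quantity from scratch.

Passing these tests shows the pipeline is internally coherent and that the
synthetic classes are learnable at the published split; it does **not**
show performance on real topograms. The simulator renders clean axial maps
with ideal palettes: it has no Placido-ring artifacts, no specular
highlights, no printer gamut distortion, no patient-specific irregular
astigmatism beyond its five stylised variants, and its "examiner" is an
iso-power oracle rather than a finger on a touchscreen. The published
confusion fixture is reproduced exactly because it is arithmetic on fixed
counts; the original per-image predictions are not recoverable.

## Numerical choices and degenerate inputs

* Homography estimation refuses collinear corner triples
  (degenerate-geometry error); corner residuals are < 1e-9 px by
  construction.
* Bilinear warping clamps sample coordinates with a 1e-6 px epsilon so
  identity warps are exact; corners may poke up to a quarter frame outside
  the capture (sampled as fill) before being rejected as erroneous.
* Achromatic pixels take hue 0 by convention; the hue plane of classifier
  inputs masks pixels with saturation ≤ 0.3 (rings, background).
* Level-set polylines with fewer than 8 vertices are discarded as noise
  specks; an empty level set raises a degenerate-pattern error.
* Exact score ties in prediction resolve to the lowest-index (least
  severe) class; a symmetry ratio exactly at threshold reads symmetric.
* Capture quads are re-drawn up to 10 times if jitter makes them
  non-convex, then error out.

## Known limitations

* The color scale and diopter span of the original topographers are not
  public; ours is a stand-in with the stated green-normal convention.
* Whether the original train/test split was random or curated is unknown;
  we use a seeded random split within class.
* Whether the original network saw the raw colors, the contour, or both
  is not stated; we default to contour-mask + hue and keep mask-only as a
  configuration.
* The rule classifier's thresholds are calibrated to the generator's
  parameter windows; real traced contours may need different settings
  (all are arguments).
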