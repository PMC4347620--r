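---
title: "Measuring beef quality parameters from carcass and ultrasound images"
author: "beefscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring beef quality parameters from carcass and ultrasound images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data

Three quality parameters of a beef carcass are estimated from images:

* **rib eye area** — the cross-sectional area of the *longissimus dorsi*
  muscle at the 12th intercostal space, from a color photograph of the cut
  surface; it indexes carcass meat yield;
* **backfat (subcutaneous fat) thickness** — the fat layer on the steak's
  outer edge, reported as a full thickness profile plus the two standard
  marks at the perpendicular projections of 1/2 and 3/4 of the rib eye's
  principal axis;
* **intramuscular fat percentage (IMF%)** — the "marbling" fraction inside
  the rib eye, regressed from the texture of a B-mode ultrasound region of
  interest; its ground truth is chemical lipid extraction, an animal-level
  measurement.

No public image database exists for this problem, so the package ships
phantom generators (`generateSteakPhantom()`, `generateUSPhantom()`,
`generateIMFDataset()`) whose outputs have exact, constructed ground truth.
Every quantitative claim the test suite or the acceptance script makes is
computed on these phantoms.

# Rib eye segmentation

## Preprocessing

The steak is bright in the red channel against a near-black background, so
background elimination is an Otsu binarization of the red channel followed
by hole filling and retention of the largest connected component
(`removeBackground()`). Otsu's criterion is implemented with the convention
that the dark class is `x < t`; the exhaustive 256-candidate minimizer is
kept as an independent oracle in the tests.

Meat and non-meat (fat, bone) are separated inside the steak by Otsu votes
on three channels — u and L of CIE Luv (D65 white point, fixed because the
thresholds depend on it) and G of RGB — combined by majority by default
(`detectMeatNonmeat()`). Meat is the darker class in G and L and the
higher-u class (lean muscle is red; fat and bone are bright and nearly
achromatic). A channel only votes when its Otsu split is genuinely bimodal:
the separability $\eta$ (between-class over total variance) must exceed
0.75. The threshold sits between what an optimal split of pure noise
achieves (~0.64) and real meat/fat splits (>0.99). An all-fat steak
therefore yields an empty meat mask with a warning rather than a noise
partition.

## Edge fields and curve evolution

Contours evolve under a distance-regularized level-set scheme with a
geodesic edge indicator

$$g = \frac{1}{1 + |\nabla G_\sigma * I|^2}, \qquad \sigma = 1.5\ \text{px},$$

computed on two inputs: the **high-contrast** field from the binary
non-meat mask (scaled 0/255) and the **emphasized** field from the u
channel after Perona–Malik anisotropic diffusion (15 iterations,
conduction coefficient 30 on the 8-bit scale, time step 0.15 — within the
0.25 stability bound of the 4-neighbor discretization).

The level-set field is initialized as a signed distance function of a seed
region obtained by eroding the meat mask (3×3 cross) until a single
connected component survives, after discarding components under 1% of the
meat area. Because the rib eye is the largest meat region, the survivor
lies inside it.

Evolution runs in three stages:

1. fast expansion against the high-contrast field alone (balloon weight
   −3, growth checked every 20 iterations);
2. slower evolution adding the emphasized energy — the two fields are
   combined as their pointwise minimum — with balloon −1.5, checks every
   10 iterations, and a stop when the interior grows by less than 0.5%
   between checks (the stop threshold is exposed and can be recalibrated
   on labeled phantoms);
3. exactly ten refinement iterations with no balloon force.

Default dynamics are time step 5, regularization weight 0.04 (product
0.2 < 1/4, the stability requirement), length weight 5, Dirac width 1.5.

Two numerical choices matter and are deliberate:

* **Edge tempering.** A binary input scaled to 0/255 drives $g$ to ~10⁻⁴
  over a ±3 px valley around each edge; every force in the model is
  proportional to $g$ or $\nabla g$, so the front stalls at the valley
  *entrance*, a systematic ~3 px under-segmentation (~8% area error on
  typical phantom geometry). The stages therefore evolve against
  $g^{0.3}$ — a monotone transform that moves no minimum but lifts the
  valley floor so the balloon carries the front to the valley center,
  where the geodesic attraction pins it. The exponent is exposed as
  `edgeExponent`; 0.3 was chosen over smaller values because the
  attraction on the valley's far slope must dominate the balloon force
  with a margin, otherwise the front can creep through a weak boundary
  segment and flood the fat region. The final mask is intersected with
  the steak mask (the rib eye is part of the steak by definition).
* **Stage-boundary redistancing.** The double-well potential maintains
  $|\nabla\varphi| \approx 1$ only within a couple of pixels of the zero
  level; farther out it drives the field toward its flat well. Each stage
  therefore re-anchors $\varphi$ to an exact signed distance function on
  return (the zero level set — and hence the mask — is unchanged). After
  every stage, at least 95% of the pixels within 5 px of the contour have
  $|\nabla\varphi| \in [0.8, 1.2]$; `bandGradientFraction()` measures
  this.

The area is the interior pixel count of the final zero level set.

# Backfat thickness

The inner curve is the convex hull of the meat; the outer (target) curve
is the boundary of the union of the steak region and the hull region.
Where the two would touch, the union is locally dilated by 2 px so the
curves never intersect. Control points on the inner curve — uniform
arc-length samples at ~50 px spacing, mirroring evolution on a
1/50-density resampling of the dense contour — march along their outward
normals in 1 px steps until they come within one step of the target;
points are created when neighbors drift beyond twice the spacing and
merged below a quarter of it. The thickness at a point is its cumulative
path length. Because the target lives on a raster, its interpolated
distance field bottoms out around half a pixel; arrival therefore uses a
tolerance of `max(step, 0.75)` px, without which a sub-pixel step could
never terminate.

The principal axis of the rib eye comes from image moments (centroid plus
the major axis of the second central moments, canonicalized to a positive
x component); the two standard marks are the feet of the perpendiculars at
1/2 and 3/4 of the axis, inserted as anchor control points so the marks
are measured exactly. The backfat side of the axis is `"down"` by default:
the acquisition protocol orients the cut consistently, and the automatic
alternative (pick the side with the larger curve separation at the feet)
can mis-pick when the fat rim plus hull-chord gaps on the far side exceed
a thin band. All thicknesses are in pixels; a physical scale converts them
only when supplied.

# Ultrasound ROI and IMF%

The subcutaneous fat band is the labeled bright component (Otsu on the raw
frame) whose centroid lies in the upper third and whose width/height ratio
is largest. Ribs are found by normalized cross-correlation — computed with
box-filter running sums — between the diffused frame and a synthetic,
column-symmetric rib template (Gaussian-blurred bright arc of radius
0.4 × width over a dark shadow), followed by non-maximum suppression in a
31×31 window; the two strongest admissible maxima (correlation ≥ 0.5,
horizontal separation ≥ W/4) are the ribs. The 80×80 ROI is centered
horizontally between the ribs and vertically midway between the band's
lower edge and the mean rib depth; a zone smaller than the square raises
an error so a caller can fall back to a manual ROI.

Each ROI yields a 42-feature descriptor (`imfFeatureNames()` is the
authoritative order): gradient mean/sd at two smoothing scales (4);
co-occurrence correlation, homogeneity, contrast and energy at 32 gray
levels for offsets (0,1), (1,0), (1,1), (1,−1) (16); gray-level mean,
contrast ratio and entropy (3); histogram percentiles 20/40/60/80 and
skewness (5); Fourier variance coefficient and five log-power percentiles
(6); LBP(8,1) uniform-code co-occurrence statistics (4) and code-histogram
statistics (4). Degenerate inputs use fixed conventions: any
variance-normalized statistic is 0 when the variance vanishes, so a
constant patch is a valid input. Features are standardized and reduced to
10 principal components, then an RBF-kernel support vector regressor is
fitted; the kernel width γ (grid 2⁻¹⁰…2³) and termination tolerance
(10⁻⁴, 10⁻³, 10⁻²) are chosen by 5-fold cross-validated RMSE on the
training split only, with the regularization constant fixed at 1.

# Phantom generators

The steak phantom is an elliptical body with an elliptical rib eye,
satellite muscle blobs, white fat seams, and a backfat band rendered
outside the body along a [0.2π, 0.8π] arc with an arc-parameterized
thickness function. A thin meat strip lines the body boundary along the
band arc and the satellites sit near the boundary, so the meat convex hull
reaches the inner band edge and the band thickness function is exactly the
hull-to-target distance — this is what makes the constructed thickness
profile a usable ground truth. The band arc is wide enough that the
3/4-axis perpendicular stays on the band across the sampled rib eye
rotations (±0.3 rad). Colors are flat (meat ~(168,45,52), fat
~(243,238,228)) with Gaussian pixel noise (σ = 3 by default).

The ultrasound phantom renders skin, a bright fat band, muscle, two rib
echoes stamped from the same template family the detector uses, and bright
intramuscular specks whose per-pixel density is affine in a latent IMF
scalar in [0, 10] (0.002 + 0.0035 × scalar). Everything is multiplied by a
Rayleigh-like speckle envelope — (1−w) + w·R with R a normalized squared
low-pass Gaussian field, w = 0.4, correlation length 1.2 px. This emulates
the *appearance* of B-mode speckle and a monotone texture–IMF
relationship; it is not a physical ultrasound simulation (no point-spread
function, no attenuation), so passing tests demonstrate correct mechanics
and recoverability under the stated noise, not clinical performance on
real probes.

The IMF dataset draws one latent scalar per animal (uniform on [0, 10]),
renders 4 frames per animal (69 animals, 276 images by default), and
assigns one label per animal, `2 + 0.8·scalar + N(0, 0.3)` — the noise
magnitude matches the reported error of chemical lipid extraction
(< 0.3%). Splits are made per animal (46/23 animals, hence 184/92 images),
never per image, so frames of one animal cannot leak across the split.

The split protocol's training fraction defaults to 0.67, the two-decimal
form of the nominal 2/3. The distinction matters: the reference split
sizes of the two protocols are 103/50 of 153 observations and 46/23
animal groups, and `round(n * 0.67)` reproduces both, whereas an exact
2/3 of 153 is 102. Any other fraction can be passed explicitly.

# Problem sizes and reproducibility

The validation suites use 320×320 phantoms (the analytic ellipse case
420×440), 20 seeds for the rib eye and backfat suites, 100 seeds for ROI
detection, and 100 repeated splits of the 276-image IMF dataset. Every
generator is a pure function of its specification and seed, all
randomness flows through explicit seeds, and `segmentRibeye()` is fully
deterministic, so identical inputs reproduce identical masks, profiles and
reports byte for byte.

# Known limitations

* Phantom colors are flat; no color calibration or white-balance handling
  is attempted, and the Luv thresholds assume D65.
* The level-set machinery targets a single rib eye (the largest meat
  region); adjacent muscles are excluded by erosion and edge energy, not
  labeled.
* The backfat "auto" side heuristic assumes the backfat is the thickest
  fat structure at the mark feet; frames with unusual trim need the
  explicit `side` argument.
* The speckle model is phenomenological; texture features transfer to real
  B-mode data only after retraining on labeled images.
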