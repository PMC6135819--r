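---
title: "Methods: robust 3D nuclear and nucleolar morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: robust 3D nuclear and nucleolar morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Changes in the shape of the cell nucleus and its nucleoli accompany
differentiation, proliferation, mechanical stress, and disease, but
voxel-level measurements on segmented 3D masks are noisy, pose-dependent,
and blind to fine geometry. `nucmorph3d` models each segmented object as a
smooth, closed, genus-zero surface and derives a small set of
interpretable geometric biomarkers from that surface: volume (V), surface
area (SA), and area-weighted means of mean curvature (MC), shape index
(SI), curvedness (CV), plus a box-counting fractal dimension (FD). Nuclear
and nucleolar measures are combined into fixed-length per-nucleus feature
vectors, and condition discrimination is evaluated with grouped
cross-validation and cell-set (majority-vote) classification.

## Surface reconstruction

The reconstruction treats a binary mask as a discretized indicator
function and extracts a smooth boundary in five steps:

1. **Prepare the mask.** Internal cavities (background not reachable from
   the grid border under 6-connectivity) are filled, and critical 2x2(x2)
   configurations are repaired so the image is *well-composed*: its
   boundary is then guaranteed to be a 2-manifold. Foreground uses
   26-connectivity, background 6-connectivity throughout.
2. **Mesh the boundary** with marching tetrahedra on the voxel-center
   lattice (Kuhn 6-tetrahedron decomposition, consistent across cells,
   watertight by construction). Vertices sit at midpoints between
   foreground and background voxel centers.
3. **Condition the mesh** with Taubin lambda/mu smoothing (10 pass pairs,
   lambda = 0.5, mu = -0.53). The marching mesh carries half-voxel
   staircase oscillation; Taubin smoothing damps it with negligible
   volume change. Without this step the spectral projection below retains
   enough staircase ripple to bias surface area by several percent and to
   corrupt local curvature (measured sphere SI drops from ~0.98 to ~0.80).
4. **Project onto the Laplace-Beltrami eigenbasis.** The cotangent
   stiffness matrix and lumped (barycentric) mass matrix define the
   discrete LB operator; the k eigenfunctions with smallest eigenvalues
   form a Fourier-like basis on the surface, and the three coordinate
   functions are replaced by their projection onto that span — a spectral
   low-pass on shape. Default k = 100 keeps the low-frequency content that
   describes nucleus-like shapes. Small problems use a dense solver; large
   ones shift-inverted Lanczos iteration on the mass-symmetrized operator.
5. **Locate and remove spurious features.** The per-vertex displacement
   between the conditioned boundary and its projection, normalized by the
   mean edge length, is the *metric distortion*. Boundary voxels whose
   nearest vertices exceed a distortion threshold are removed — but only
   if they are *simple points* under the (26, 6) pair, so the flip can
   never change foreground or background topology. Steps 2-5 iterate
   until no voxel flips, the flip count stops decreasing, or 10
   iterations; the returned surface is the eigen-projection of the final
   boundary.

### The distortion threshold

The threshold is scale-free (units of mean edge length). On clean solids
— spheres, ellipsoids, and even cubes and octahedra whose sharp edges the
projection genuinely rounds — the measured distortion stays below ~1.8,
while a 5-voxel segmentation spike already measures above 2.2. The
default threshold of 2.0 therefore removes artifact-scale features
without eroding real geometry. An adaptive alternative
(3 x median distortion, `distortion_threshold = NULL`) is available but
systematically trims the genuine edges of faceted objects: on a 24-voxel
cube it inflates the surface-area error from ~5.5% to ~8%, so it is not
the default. The flip-plateau stopping rule exists for the same reason:
once the flip count stops shrinking, further flips remove real boundary,
not artifacts.

## Morphometric measures

Principal curvatures come from discrete estimates on the triangulation:
mean curvature H from the cotangent mean-curvature normal (signed by the
outward vertex normal, so convex regions are positive), Gaussian
curvature K from the angle deficit, both over barycentric vertex areas,
and then k1,2 = H -/+ sqrt(max(H^2 - K, 0)). The derived fields follow the
closed forms MC = (k1+k2)/2, SI = (2/pi) arctan((k1+k2)/(k2-k1)) in
[-1, 1], CV = sqrt((k1^2+k2^2)/2).

Two numerical choices matter:

* **Mean-preserving field regularization.** H and K estimates on marching
  meshes are noisy, and the noise enters the k1/k2 split asymmetrically:
  it deflates SI and inflates CV while leaving the mean of H unbiased.
  Both fields are therefore smoothed by implicit heat diffusion,
  solving (M + tL) x' = M x with diffusion length 4 mean edge lengths.
  Because the row sums of L vanish, this preserves the area-weighted mean
  of each field *exactly* — mean MC and the MC-dominated part of CV are
  untouched — while local noise anisotropy is suppressed (reconstructed
  sphere: SI 0.80 -> 0.98, CV bias +12% -> +0.1%).
* **Area weighting.** All reported curvature means are weighted by the
  barycentric vertex area (one third of incident triangle area), making
  them insensitive to mesh resolution. Whether uniform or area-weighted
  vertex averaging is the "right" convention is underdetermined in the
  morphometry literature; area weighting is this package's documented
  choice.

Volume is the signed-tetrahedron sum (discrete divergence theorem),
surface area the triangle-area sum. The fractal dimension fits
log N(eps) against log(1/eps) for boxes of 1/4 ... 1/32 of the largest
extent, counting boxes hit by a dense deterministic sampling of the
triangulation (sample spacing a quarter of the smallest box). Two
choices stabilize the estimate: boxes are aligned to the principal axes
of the vertex cloud, making it invariant under rigid motion, and counts
are averaged over three shifted box-grid origins, damping the arbitrary
lattice alignment. Smooth surfaces score ~2.0; roughness raises the
value. A sanity band of [1.5, 3] applies; the coarse scale ladder is
kept fixed for comparability rather than tuned per object, and residual
estimator noise between two voxelizations of the same shape is about
0.03-0.05, which is why cross-pose FD comparisons use an absolute band
rather than the 1% relative band of the surface measures.

## Feature assembly

Each nucleus record contains the 6 nuclear measures, the nucleolus count,
and Avg/Min/Max/Var of each of the 6 measures across its nucleoli —
31 features regardless of how many nucleoli a nucleus has. Variance is
the sample variance (n - 1), zero for a single nucleolus. "Higher
moments" beyond the variance (skewness, kurtosis) are deliberately not
included: only the four Avg/Min/Max/Var families appear in the feature
set. Nucleoli are matched to the unique nucleus containing their centroid
(robust to boundary-touching voxels); nucleoli outside every nucleus are
dropped, and nuclei without nucleoli are excluded so all feature vectors
have equal length. When several nucleolar channels exist (e.g.
anti-fibrillarin and EtBr), each provided volume is processed
independently — the package does not merge channels.

## Classification

Leave-2-Opposite-Groups-Out (L2OGO) cross-validation builds one fold per
opposite-class image pair: all objects from an image stay on one side of
the split, and every test set holds exactly two images of different
classes, guarding against image-level batch effects. Training classes are
balanced by uniform sub-sampling to the minority count. Two presets
mirror the published configurations: `fibroblast-gb` (stochastic gradient
boosting, 1,500 learners, depth 8, subsample 0.5, via xgboost with
learning rate 0.1) and `pc3-rf` (random forest, 1,000 trees, depth 12,
40% features per split, via ranger); `fast-rf` is a light forest for
synthetic populations and tests.

Cell sets of size 3-31 are drawn with replacement from a single test
image per draw (so each set has one true label), 1,000 bootstrap
repetitions per fold. A set is labeled by the majority of member hard
labels (0.5 probability threshold), ties broken by the mean member
probability, and scored by the mean probability for set-level AUC — the
vote-fraction alternative is not used. Metrics (accuracy, precision,
sensitivity, rank-statistic AUC) are computed per repetition over that
repetition's sets, averaged over repetitions, and summarized as
mean +/- SD across folds. Under independent per-cell accuracy p the
majority vote follows the exact binomial tail, which the test suite
checks at p = 0.7, set size 19.

## Synthetic phantoms and what they show

`make_phantom()` rasterizes spheres, ellipsoids, cubes, octahedra
(L1 ball, circumradius c: V = 4c^3/3, SA = 4*sqrt(3)c^2), and three
overlapping spheres with linearly aligned centers (inclusion-exclusion
volume over the two lens intersections, valid while the outer spheres
stay disjoint) by voxel-center membership — matching binary-mask
semantics, no anti-aliasing. Triaxial ellipsoid area uses Gauss-Legendre
quadrature of the parametric surface integral.

The validation roster (`validate_synthetic()`, 128^3 grids) covers the
two accuracy regimes: smooth nucleus-like shapes (sphere r = 20,
ellipsoid 26 x 20 x 15.4) where volume and area errors stay well inside
2%, and faceted shapes (cube s = 24, octahedron c = 24) where spectral
rounding of curvature singularities keeps errors inside 6%.

The qualitative curvature ordering (mean MC and CV: sphere < ellipsoid <
overlapping spheres; SI highest for the sphere) is checked with a sphere
(r = 20), an *elongated* prolate ellipsoid (35 x 15 x 15), and overlap
r = 12 / offset 16. The shape choice is deliberate: quadrature on the
implicit surface shows an equal-volume triaxial ellipsoid
(26 x 20 x 15.4) has true area-weighted mean MC of 0.04998 —
indistinguishable from the sphere's 0.05 — and the concave neck of an
overlap configuration contributes a negative turning-angle term that is
independent of the fillet radius, so wide-neck overlaps can fall below
elongated ellipsoids. The ordering is a geometric fact only for shape
families like the trio above, and that is where it is asserted.

`make_population()` emulates the structure of a two-condition dataset:
images per condition, several nuclei per image, 1-4 spherical nucleoli
inside each nucleus, per-axis scale jitter U(1 - j, 1 + j) with j = 0.06,
random orientation, one seeded generator. Defaults (spheres r = 10 vs
volume-matched prolate ellipsoids 13 x 10 x 7.7, 36-voxel cells) create a
population separable mainly through ShapeIndex — by design, since the
pipeline's job is to recover shape, not intensity. What passing tests on
this population do *not* show: robustness to real segmentation errors,
intensity/texture effects, anisotropic point-spread blur, or touching
nuclei; the generator produces clean masks only.

## Problem sizes and degenerate inputs

Default problem sizes were chosen as the smallest that keep
discretization error far from the tested tolerances: 128^3 grids for
phantom validation, 40^3 for the randomized topology suite (50 shapes),
3 images per class x 5-6 nuclei for classification demonstrations.
Objects below 8 voxels refuse to mesh; components below `min_voxels`
(default 50) are discarded as segmentation specks. Masks touching the
grid border are zero-padded (or rejected when `pad = FALSE`). Degenerate
one-rings in curvature estimation are imputed from the field median and
reported. Eigen-projection with k >= n reproduces the input mesh, and
requesting k < 4 is an error.

## Known limitations

* Genus-zero topology is enforced, not inferred: objects that are truly
  toroidal will be repaired (cavity fill, largest component) or rejected.
* The fractal dimension is a box-counting estimate over a fixed, coarse
  scale ladder; it is comparable across objects processed identically but
  is not an absolute dimension estimate.
* The classifier stage expects binary conditions; multi-class designs
  require one-vs-one reduction outside the package.
* Reported SI/CV/MC depend on the documented smoothing scales (Taubin
  passes, diffusion length); changing them changes absolute values, so
  comparisons should hold them fixed.
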