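# nucmorph3d

3D morphometry of cell nuclei and nucleoli from binary segmentation
masks, in R.

Quantifying how nuclear and nucleolar shape changes with cell state
(proliferation, serum starvation, epithelial–mesenchymal transition, …)
requires measures that live on the object's *surface*, not on raw voxels:
voxel masks are noisy, pose-dependent, and hide fine geometry. This
package is for microscopy groups who already have segmented 3D masks
(multi-page TIFF stacks) and want robust, interpretable per-object shape
biomarkers plus a defensible classification protocol on top of them.

## What it computes

1. **Robust genus-zero surface reconstruction.** Each mask is filled,
   repaired to be well-composed, meshed by marching tetrahedra,
   conditioned, and projected onto the span of the first *k*
   eigenfunctions of its Laplace–Beltrami operator — a Fourier-like
   low-pass on shape. Metric distortion between boundary and projection
   localizes spurious features, which are removed voxel-by-voxel under a
   simple-point test that provably preserves topology; the loop iterates
   to convergence.
2. **Six morphometry measures** per object: volume `V`, surface area
   `SA`, and area-weighted means of mean curvature `MC = (κ₁+κ₂)/2`,
   shape index `SI = (2/π)·arctan((κ₁+κ₂)/(κ₂−κ₁)) ∈ [−1,1]`, curvedness
   `CV = √((κ₁²+κ₂²)/2)`, plus the box-counting fractal dimension `FD`.
3. **Nucleus feature vectors**: the 6 nuclear measures + nucleolus count
   + Avg/Min/Max/Var of each measure over the nucleus's nucleoli
   (31 features, fixed length).
4. **Cell-set classification** under Leave-2-Opposite-Groups-Out (L2OGO)
   cross-validation: every fold tests on two whole images of opposite
   class; sets of 3–31 cells are bootstrap-sampled (1,000 repetitions)
   within a test image and labeled by majority vote, with accuracy,
   precision, sensitivity, AUC, and cross-validated feature importance.
5. **Synthetic phantoms** (spheres, ellipsoids, cubes, octahedra,
   overlapping spheres, and labeled two-class populations) with
   closed-form references, so the whole pipeline is testable without any
   external dataset.

## Worked example

```r
library(nucmorph3d)

# sphere phantom, radius 20 voxels on a 128^3 grid
ph  <- make_phantom(phantom_spec("sphere", c(128, 128, 128), radius = 20))
rec <- reconstruct_surface(ph$volume)          # smooth genus-zero mesh
sig <- compute_signature(rec)
round(sig[, c("Volume", "SurfaceArea", "MeanCurvature",
              "ShapeIndex", "Curvedness", "FractalDimension")], 4)
#>     Volume SurfaceArea MeanCurvature ShapeIndex Curvedness FractalDimension
#> 1 33546.83    5031.375          0.05     0.9758       0.05            2.003
```

The analytic references are `V = 4π·20³/3 ≈ 33510`, `SA = 4π·20² ≈ 5027`,
`MC = CV = 1/r = 0.05`, `SI = 1` (every point of a sphere is a convex
umbilic), `FD ≈ 2` for a smooth surface — the reconstruction lands within
0.11% on volume, 0.10% on area, and recovers the local descriptors.

A full synthetic study — two-class population, reconstruction, feature
assembly, L2OGO set classification:

```r
pop <- make_population(n_images_per_class = 3, nuclei_per_image = 6, seed = 11)
res <- run_pipeline(pop, set_sizes = seq(3, 31, 4), n_bootstrap = 300, seed = 5)
res$classification$summary      # mean accuracy / AUC per set size
head(feature_importance(res$classification), 3)
#>            feature importance
#> 1       ShapeIndex      0.490
#> 2      SurfaceArea      0.116
#> 3 FractalDimension      0.108
```

The two classes differ only in nuclear elongation (equal volumes), and
the importance ranking recovers exactly that: shape, not size, carries
the signal.

A thin command-line wrapper ships in `inst/cli/nucmorph.R`
(`generate`, `reconstruct`, `measure`, `aggregate`, `classify`,
`validate-synthetic`, `run`).

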