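---
title: "Mesh-based co-clustering of embryo gene-expression images: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesh-based co-clustering of embryo gene-expression images: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryomesh)
```

## The problem

Standardized in situ hybridization images of early *Drosophila* embryos are
roughly elliptical, laterally oriented, and mutually aligned, but each embryo
has its own shape. To compare expression across hundreds of genes we need a
common coordinate system whose cells are small, anatomically stable regions.
`embryomesh` builds that system as a triangular mesh of an *average* embryo
ellipse, carries the mesh elastically onto every image, summarizes each
element by its median intensity, and co-clusters the resulting genes ×
elements matrix so that each co-cluster pairs a gene set with the embryonic
domain where it is expressed.

This vignette records the models, the tunable parameters, and the places
where the design was genuinely open, together with the choices made.

## Geometry

**Ellipse fitting.** Boundaries are the mask's foreground pixels with a
4-connected background neighbor, ordered by Moore-neighbor tracing. The fit
is the direct algebraic least-squares conic fit with the ellipse constraint
(the numerically stable Halir–Flusser formulation), after centering and
isotropic scaling for conditioning. An algebraic fit was chosen over an
iterative geometric fit because it is closed-form and deterministic; for the
low-noise, densely sampled boundaries produced by masks the two agree
closely (the test suite checks this against a Sampson-distance oracle).

**Averaging.** The generic ellipse averages center and semi-axes
arithmetically. Rotation is averaged with a circular mean on *twice* the
angle, because ellipse orientation is π-periodic: averaging +89° and −89°
must give ±90°, not 0°. Whether to average geometric parameters or conic
coefficients was open; geometric averaging is used because each parameter
then has a direct anatomical meaning (body length, girth, tilt).

**Pixel convention.** The pixel at matrix position (row r, column c) has
center (c − 0.5, r − 0.5). Projected boundary coordinates are always pixel
centers; sub-pixel boundary localization is out of scope.

## Mesh generation

Given a triangle area budget *a*, the boundary of the generic ellipse is
subdivided into segments of approximately the equilateral side length
ℓ = √(4a/√3). Uniformity is *by segment length, not by radial angle*: on an
elongated ellipse, equal angles would crowd vertices at the poles and starve
the flanks. The subdivision walks a fixed chord around a dense (8192-sample)
polyline of the boundary and bisects on the chord length until exactly
s = ⌈perimeter/ℓ⌉ equal chords close the loop. This realizes "approximately
equal segment lengths" with a relative chord spread far below the 1%
tolerance the subdivision enforces, and is exactly deterministic. A plain
equal-arc-length placement was rejected because chord lengths then vary with
curvature and can exceed a 1% spread at the high-curvature poles of a 2:1
ellipse.

The planar straight-line graph (the closed loop plus one point at the
center) is triangulated by the package's own Delaunay refiner:

* incremental Bowyer–Watson Delaunay triangulation of the boundary vertices,
  the center, and a hexagonal interior lattice at spacing 0.88ℓ (with a
  deterministic sub-pixel jitter that removes the lattice's exactly
  cocircular quadruples);
* Laplacian smoothing of interior vertices (boundary and center fixed),
  re-triangulating as positions change;
* Steiner-point insertion — circumcenters where they fall safely inside the
  domain, centroids otherwise — for any triangle violating the area bound or
  the minimum-angle bound, interleaved with smoothing. Candidate points
  closer than 0.45ℓ to any existing vertex are rejected: this spacing filter
  keeps batched insertions from clustering (the failure mode of naive batch
  refinement, which cascades into ever-thinner triangles) and bounds the
  vertex count by a packing argument, so the loop terminates. A quality mesh
  at this sizing has no edges shorter than ≈0.5ℓ, so the filter never blocks
  an insertion the final mesh would need; violations a blocked insertion
  would have fixed are handled by the smoothing passes.

Because the subdivision vertices are in convex position, every boundary
segment is a convex-hull edge of the point set and therefore always present
in the Delaunay triangulation: the PSLG is preserved and never split. The
contract checked by the tests is the postcondition, not the construction:
all areas ≤ *a*, all angles ≥ the bound, segments unsplit, deterministic
output. The default angle bound is 25°, which is reliable for ellipse-like
domains; larger bounds are refused since refinement is then not guaranteed
to terminate.

`calibrate_area_bound()` finds *a* for a requested element count (e.g. 300,
600, 1000) by deterministic bracketing and bisection on *a*, accepting a
count within 10%.

## Deformation

The subdivision's parametric angles are evaluated on each image's fitted
ellipse and projected to the *nearest boundary pixel* (not along radial
rays, which distorts where the boundary is oblique to the ray). Ties between
equidistant boundary pixels go to the lowest (row, column) — an arbitrary
but fixed rule that the brute-force test oracle shares. If heavy boundary
noise makes the projected points lose their cyclic order around the mask
centroid, the correspondence is returned with a warning flag rather than
silently accepted.

Interior vertices follow by solving plane-stress linear elasticity with
linear (P1) triangle elements, Young's modulus 1 and Poisson ratio 0.3,
with the boundary displacements imposed exactly by system reduction
(eliminating constrained rows and columns) rather than by penalty terms.
Only the displacement field matters, so the elastic constants are a free
choice: any admissible pair reproduces affine fields exactly (the patch
test), which is the property the pipeline relies on. Folded (negatively
oriented) triangles after deformation are reported in the per-image quality
table and, in strict mode, abort.

## Expression matrix

A pixel belongs to the triangle containing its center; pixels exactly on a
shared edge go to the lowest-index incident triangle, which makes the
partition deterministic and oracle-matchable. Every pixel center inside the
deformed mesh is assigned to exactly one element; the element value is the
median intensity, robust to ISH speckle. Whether medians should be
restricted to an explicit foreground mask was ambiguous; since the deformed
mesh tessellates the embryo, "inside the mesh" is used as the foreground
definition. An element covering no pixel center (possible only for
pathological meshes) is set to 0 — keeping the matrix nonnegative and the
multinomial model valid — and flagged. Intensities are used raw in [0, 255]
with no per-image normalization.

## Co-clustering model

The matrix **A** is the weighted bipartite adjacency between genes and
elements. With column-stochastic indicators *P* (genes × c) and *Q*
(elements × c), the multinomial model's log likelihood is

$$L = 2\sum_{ij} A_{ij}\, \log\, (PQ^{\top})_{ij},$$

maximized by EM: responsibilities
$\phi_{ijk} = \hat P_{ik}\hat Q_{jk} / (\hat P\hat Q^{\top})_{ij}$
and multiplicative updates
$P_{ik} \leftarrow \sum_j \hat P_{ik}\hat Q_{jk} A_{ij}/(\hat P\hat Q^{\top})_{ij}$
(symmetrically for *Q*), then column normalization. The constant factor 2
in front of the updates cancels under normalization; the tests assert the
implementation is identical with and without it. The update never decreases
L; the trace is stored and checked.

Choices the model statement leaves open, fixed as follows:

* **Initialization / restarts:** columns of *P*, *Q* drawn i.i.d. from a
  symmetric Dirichlet (unit-shape gammas, normalized), seeded; 5 restarts,
  best final L kept.
* **Convergence:** relative L change < 1e−8 or 500 iterations (flagged when
  hit).
* **Zeros:** terms with A. = 0 contribute nothing (0·log 0 = 0); all-zero
  rows/columns are dropped with a warning and re-embedded as zero
  memberships. If A > 0 where (PQᵀ) = 0 the likelihood is −∞, reported, not
  an error.
* **Dead clusters:** a column whose normalization constant underflows is
  reinitialized from the prior once, then frozen.
* **Hardening:** labels are argmax over the indicator rows; exact ties break
  to the lowest cluster index and are logged.
* **Scale invariance:** the optimizer depends only on A's normalized
  pattern, so fits on A and 2A coincide — asserted as a test.

The number of co-clusters c is an input, not selected by the package.

## Enrichment

Over-representation of annotation terms in gene clusters uses the
hypergeometric upper tail P(X ≥ k) with the universe defaulting to all genes
in the matrix (no background set is otherwise defined). Raw p-values are
thresholded at 0.001 by default — matching the conventional raw-p report for
this analysis — with Benjamini–Hochberg adjustment available but off. Only
(cluster, term) pairs with at least one overlapping gene are tested. No
ontology-graph propagation is performed.

## The synthetic generator

The generator is the package's study condition, not a tuning dial. Defaults
emulate standardized stage 4–6 lateral embryo images:

| parameter | default | meaning |
|---|---|---|
| image size | 160 × 320 px | standardized frame |
| base ellipse | center (160, 80), semi-axes 140 × 60 px | ~2.3:1 embryo |
| boundary noise | 4 px, ≤ 5 Fourier harmonics | inter-embryo shape variation |
| background | 20 | unstained tissue gray level |
| domain levels | 200–220 | strong ISH signal |
| pixel noise | sd 6 | acquisition noise |

The boundary perturbation is a low-order Fourier series in polar angle,
rescaled to the requested maximum amplitude; that keeps the boundary smooth,
star-shaped and single-component, with radial correspondence well defined.
Amplitudes at or above 90% of the semi-minor axis are rejected as
potentially self-intersecting. Expression domains are axis-aligned boxes in
the *ellipse-normalized* (A/P, D/V) frame so one domain means the same
anatomical region in every perturbed embryo — mirroring the assumption that
the input images are standardized and consistently oriented. The default
layout plants three well-separated domains (anterior band, mid-ventral
block, posterior band) over three equal gene groups.

What the generator does *not* emulate: real ISH staining texture, probe
background gradients, multi-embryo frames, orientation errors, or stage
mixtures. Passing the planted-recovery tests therefore shows the pipeline is
correct under its stated assumptions, not that it is robust to failures of
upstream standardization.

## Problem sizes and determinism

The test suite and the acceptance script run at deliberate desk scale: a
20-embryo set meshed at ~300 elements for the mesh-requirements checks, and
a 9-gene, 3-domain planted design at ~120 elements for end-to-end recovery.
These sizes were chosen so the planted structure is comfortably identifiable
(tens of pixels per element, signal-to-background ratio ≈ 10) while a full
run stays in minutes; the statistical conclusions do not change with larger
meshes, only boundary smoothness does. Every stochastic step — image noise,
boundary perturbation, EM restarts — derives from explicit integer seeds,
and each generated image uses a seed derived from (dataset seed, image
index), so datasets are reproducible image by image. Pipeline artifacts are
written in formats with deterministic bytes (CSV/TSV/JSON and raw-raster
PNG), so a rerun's manifest checksums match exactly.

## Known limitations

* The mesher targets convex, ellipse-like domains; it is not a general PSLG
  refiner for concave or multiply connected geometry.
* The elastic deformation is linear; extreme boundary displacements can fold
  triangles (reported, not repaired), and intensity-driven registration is
  out of scope.
* The co-clustering likelihood is non-convex: different seeds can reach
  different local optima. Restarts mitigate but do not eliminate this.
* Enrichment treats terms independently (no ontology structure) and reports
  raw p-values by default.
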