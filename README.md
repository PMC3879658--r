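# embryomesh

Mesh-based spatial analysis of *Drosophila* embryo gene-expression images.

Genome-scale in situ hybridization (ISH) image collections show *where* each
gene is expressed in the early embryo, but embryos differ in shape, so images
cannot be compared pixel by pixel. `embryomesh` registers a whole image set
onto one shared geometry and then finds co-expressed embryonic domains:

1. **Ellipse fitting.** Each embryo's boundary pixels are fitted with an
   ellipse *E*ⱼ by direct least squares; the per-image ellipses are averaged
   into a generic ellipse *E*′.
2. **Quality meshing.** The boundary of *E*′ is subdivided into segments of
   approximately equal length ℓ = √(4a/√3) (the side of an equilateral
   triangle of area *a*), and the interior is tessellated by Delaunay
   refinement so that every triangle has area ≤ *a* and every interior angle
   ≥ 25°, with the boundary segments preserved unsplit.
3. **Elastic deformation.** The generic mesh is carried onto each embryo:
   boundary vertices move to the nearest embryo boundary pixels (Euclidean
   distance, with deterministic tie-breaking) and interior vertices follow by
   solving a plane-stress linear-elasticity finite-element problem. All
   deformed meshes share one triangle list, so element *i* means the same
   anatomical location in every image.
4. **Expression matrix.** The median gray intensity of each mesh element in
   each image yields a nonnegative matrix **A** (gene images × elements).
5. **Co-clustering.** **A** is treated as the weighted bipartite graph between
   genes and elements and factored with a multinomial model: column-stochastic
   indicator matrices *P* (m×c) and *Q* (n×c) maximize
   L = 2 Σᵢⱼ Aᵢⱼ log (PQᵀ)ᵢⱼ
   by an EM algorithm with multiplicative updates. Hardening the soft
   memberships gives c co-clusters, each a set of genes plus the embryonic
   domain where they are co-expressed.
6. **Enrichment.** Gene clusters are scored against an annotation table with
   the hypergeometric upper tail, P(X ≥ k), flagged at p < 0.001.

A synthetic-embryo generator (perturbed ellipse boundary, planted expression
domains, pixel noise) provides ground truth for every stage, so the whole
pipeline is testable without any external image collection.

The package is intended for computational biologists working with
standardized 2D expression images and for method developers who need a
reproducible, fully testable registration-plus-biclustering pipeline.

## Worked example

```r
library(embryomesh)

spec <- synthetic_spec(n_genes = 9, seed = 421)   # 3 planted gene groups x 3 domains
ds   <- generate_dataset(spec)
cfg  <- pipeline_config(out_dir = "demo_out", n_clusters = 3,
                        images = ds$images, table = ds$table,
                        masks = lapply(ds$truths, function(t) t$mask),
                        target_elements = 120, seed = 7)
res <- run_pipeline(cfg)

res$mesh
#> <tri_mesh> 68 vertices, 112 triangles (22 boundary vertices)
#>   min angle 31.66 deg (bound 25), max area 375.446 (bound 390.283)

glance(res$model)
#> # A tibble: 1 x 6
#>       c   loglik n_iter converged best_restart n_restarts
#>   <int>    <dbl>  <int> <lgl>            <int>      <dbl>
#> 1     3 -637738.    151 TRUE                 4          5

head(hard_assignments(res$model)$rows, 3)
#> # A tibble: 3 x 3
#>   row_id gene_id cluster
#>   <chr>  <chr>     <int>
#> 1 img001 gene001       3
#> 2 img002 gene002       2
#> 3 img003 gene003       1
```

The mesh summary confirms the quality bounds (all angles above 25°, all
areas below the 390.3 px² bound calibrated for ~120 elements); the model
summary reports the converged log-likelihood of the multinomial
factorization; and the gene assignment recovers the three planted groups
exactly (genes 1, 4, 7 together, etc. — adjusted Rand index 1.0 against the
generator's labels). `demo_out/` then
contains every intermediate artifact: `ellipses.json`, the `mesh/` bundle,
per-image deformed vertices, `expression_matrix.csv`, the model and
assignments, the cluster rendering PNG, and a `manifest.json` with MD5
checksums that reproduce exactly on reruns.

`autoplot(res$mesh, fill = res$assignment$columns$cluster)` draws the
co-expression domains on the generic ellipse; `autoplot(res$model)` shows the
(non-decreasing) EM trace.

A command-line front end with the same stages (`synth`, `fit-ellipses`,
`mesh`, `deform`, `matrix`, `cocluster`, `enrich`, `render`, `run`) is
installed at `inst/cli/embryomesh.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/embryomesh.R", package="embryomesh"))')" \
    synth --out work --n-genes 12 --seed 1
Rscript .../embryomesh.R run --input work/synth --out work --n-elements 300 --n-clusters 5
```

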