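Package: embryomesh
Title: Mesh-Based Spatial Gene-Expression Analysis of Drosophila Embryo Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts standardized Drosophila embryo gene-expression images into a
    genes-by-mesh-elements data matrix and co-clusters genes and embryonic domains.
    Embryo boundaries are fitted with ellipses by least squares and averaged into a
    generic ellipse, whose interior is tessellated by a quality Delaunay triangulation
    (area and minimum-angle bounds, boundary segments preserved). The generic mesh is
    deformed onto each embryo by projecting boundary vertices to the nearest boundary
    pixels and solving a linear-elastic finite-element problem for the interior.
    Median element intensities form a nonnegative matrix that is co-clustered with an
    EM algorithm for a multinomial bipartite-graph model, and gene clusters are scored
    by hypergeometric annotation enrichment. Includes a synthetic-embryo generator
    with planted co-expression domains for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
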