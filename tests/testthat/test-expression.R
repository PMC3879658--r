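# a tiny fixed mesh: unit square split into two triangles, scaled to pixels
square_mesh <- function(scale = 6, origin = c(2, 2)) {
  v <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)) * scale +
    matrix(origin, 4, 2, byrow = TRUE)
  tr <- rbind(c(1L, 2L, 3L), c(1L, 3L, 4L))
  list(vertices = v, triangles = tr)
}

test_that("a constant image yields constant element medians", {
  sq <- square_mesh()
  img <- matrix(37, 12, 12)
  med <- element_medians(img, sq$vertices, sq$triangles)
  expect_equal(as.numeric(med), c(37, 37))
})

test_that("medians follow the assigned pixel values exactly", {
  sq <- square_mesh()
  img <- matrix(0, 12, 12)
  pmap <- embryomesh:::pixel_triangle_map(sq$vertices, sq$triangles, dim(img))
  px1 <- which(pmap == 1L)
  # a triangle covering pixels valued {1, 2, 100, ...} has the plain median
  img[px1] <- 2
  img[px1[1]] <- 1
  img[px1[2]] <- 100
  med <- element_medians(img, sq$vertices, sq$triangles)
  expect_equal(med[1], stats::median(img[px1]))
  expect_equal(stats::median(c(1, 2, 100)), 2)  # the worked 3-pixel case
})

test_that("vectorized pixel assignment matches the brute-force rasterization oracle", {
  set.seed(5)
  e <- ellipse(20, 14, 16, 10, theta = 0.25)
  mesh <- mesh_ellipse(e, area_bound = 40)
  img <- matrix(round(runif(28 * 40, 0, 255)), 28, 40)
  fast <- element_medians(img, mesh$vertices, mesh$triangles)
  slow <- bf_element_medians(img, mesh$vertices, mesh$triangles)
  expect_equal(as.numeric(fast), slow)
})

test_that("every pixel inside the mesh is assigned to exactly one triangle", {
  mesh <- small_mesh()
  H <- 120; W <- 200
  pmap <- embryomesh:::pixel_triangle_map(mesh$vertices, mesh$triangles, c(H, W))
  # pixel partition: per-element counts sum to the number of pixel centers
  # inside the boundary polygon (computed independently)
  poly <- mesh$vertices[mesh$boundary_vertex_ids, ]
  xs <- rep(seq_len(W) - 0.5, each = H); ys <- rep(seq_len(H) - 0.5, times = W)
  inside <- embryomesh:::point_in_polygon(cbind(xs, ys), poly)
  expect_equal(sum(pmap > 0), sum(inside))
  img <- matrix(1, H, W)
  med <- element_medians(img, mesh$vertices, mesh$triangles)
  expect_equal(sum(attr(med, "n_pixels")), sum(inside))
})

test_that("an element covering no pixel center is zeroed and flagged", {
  v <- rbind(c(2.1, 2.1), c(2.4, 2.1), c(2.2, 2.4),  # sliver inside one pixel
             c(2.1, 6.1), c(8.4, 6.1), c(2.2, 9.4))
  tr <- rbind(c(1L, 2L, 3L), c(4L, 5L, 6L))
  img <- matrix(9, 12, 12)
  expect_warning(med <- element_medians(img, v, tr), "no pixel")
  expect_equal(as.numeric(med), c(0, 9))
  expect_equal(attr(med, "empty_elements"), 1L)
})

test_that("matrix assembly follows the table and recovers planted domains", {
  run <- planted_run()
  A <- run$res$matrix
  spec <- run$spec
  expect_s3_class(A, "expression_matrix")
  expect_equal(dim(unclass(A)), c(9L, nrow(run$res$mesh$triangles)))
  expect_true(all(A >= 0))
  expect_equal(rownames(A), run$ds$table$image_id)
  # permuting the table rows permutes the matrix rows identically
  perm <- c(3, 1, 2, 9, 5, 4, 8, 7, 6)
  A2 <- assemble_matrix(run$ds$table[perm, ], run$res$inputs$images[perm],
                        local({
                          d <- run$res$deformed
                          d$vertices <- d$vertices[perm]
                          d$ids <- d$ids[perm]
                          d
                        }))
  expect_equal(unclass(A2), unclass(A)[perm, ], ignore_attr = TRUE)
  expect_equal(rownames(A2), rownames(A)[perm])
  # planted domains: member-gene rows sit near the domain level inside the
  # domain's elements and near background elsewhere
  truth <- gene_truth_labels_of(spec)
  mesh <- run$res$mesh
  avg <- run$res$fits$average
  # per-element vertex coordinates in the normalized frame; an element is
  # "strictly inside" a region when all three vertices are, with margin
  vu <- embryomesh:::ellipse_normalize(avg, mesh$vertices[, 1], mesh$vertices[, 2])
  el_uv <- function(j) vu[mesh$triangles[, j], , drop = FALSE]
  uu <- cbind(el_uv(1)[, 1], el_uv(2)[, 1], el_uv(3)[, 1])
  vv <- cbind(el_uv(1)[, 2], el_uv(2)[, 2], el_uv(3)[, 2])
  lay <- spec$domain_layout
  strict_in <- function(r, margin = 0.04) {
    apply(uu >= lay$u_min[r] + margin & uu <= lay$u_max[r] - margin &
            vv >= lay$v_min[r] + margin & vv <= lay$v_max[r] - margin, 1, all)
  }
  any_dom <- Reduce(`|`, lapply(seq_len(nrow(lay)), function(r) {
    apply(uu >= lay$u_min[r] - 0.04 & uu <= lay$u_max[r] + 0.04 &
            vv >= lay$v_min[r] - 0.04 & vv <= lay$v_max[r] + 0.04, 1, any)
  }))
  rim <- apply(uu^2 + vv^2 > 0.85^2, 1, any)
  for (g in c(1, 5, 9)) {
    dom <- truth[g]
    lvl <- lay$level[dom]
    in_el <- which(strict_in(dom) & !rim)
    out_el <- which(!any_dom & !rim)
    expect_gt(length(in_el), 3)
    expect_lt(max(abs(A[g, in_el] - lvl)), 25)
    expect_lt(max(abs(A[g, out_el] - spec$background_level)), 25)
  }
  long <- tidy(A)
  expect_equal(nrow(long), nrow(A) * ncol(A))
})
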