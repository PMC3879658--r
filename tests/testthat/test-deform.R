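test_that("projection fixes boundary pixels and solves the 3-4-5 case", {
  m <- disc_mask(10)
  bp <- embryomesh:::boundary_pixel_set(m)
  onb <- project_to_boundary(bp[1:5, , drop = FALSE], m)
  expect_equal(cbind(onb$x, onb$y), unname(bp[1:5, , drop = FALSE]))
  expect_equal(onb$distance, rep(0, 5))
  # single-pixel mask: its center is the only boundary pixel; a query offset
  # by (3, 4) projects onto it at distance exactly 5
  single <- matrix(FALSE, 12, 12)
  single[8, 9] <- TRUE
  pr <- project_to_boundary(matrix(c(8.5 - 3, 7.5 - 4), 1), single)
  expect_equal(c(pr$x, pr$y), c(8.5, 7.5))
  expect_equal(pr$distance, 5)
  expect_error(project_to_boundary(matrix(c(1, 1), 1), matrix(FALSE, 4, 4)),
               "boundary|empty")
})

test_that("distance-transform projection matches the brute-force oracle including ties", {
  set.seed(77)
  m <- disc_mask(12)
  n <- nrow(m)
  pts <- cbind(runif(150, 1, n - 1), runif(150, 1, n - 1))
  # integer- and half-integer-coordinate queries force exact distance ties
  grid <- as.matrix(expand.grid(x = c(6, 12, 12.5, 18), y = c(6, 12, 12.5, 18)))
  pts <- rbind(pts, grid, grid + 0.5)
  pr <- project_to_boundary(pts, m)
  bf <- bf_project(pts, m)
  expect_equal(cbind(pr$x, pr$y), unname(bf))
})

test_that("correspondence projects ellipse vertices onto the embryo boundary in order", {
  e <- ellipse(40, 30, 30, 20)
  m <- raster_ellipse_mask(e, 60, 80)
  sub <- subdivide_boundary(e, equilateral_side(60))
  co <- correspond_and_project(e, sub, m)
  # self-projection: the mask is the rasterized ellipse, so displacements are
  # at most a pixel diagonal
  expect_lt(max(co$distance), sqrt(2))
  expect_true(attr(co, "ordered"))
  # radially dilated mask: displacements track the 5 px offset
  m5 <- raster_ellipse_mask(ellipse(40, 30, 35, 25), 60, 80)
  co5 <- correspond_and_project(e, sub, m5)
  disp <- sqrt((co5$px - co5$ex)^2 + (co5$py - co5$ey)^2)
  expect_true(all(disp >= 4 & disp <= 6))
})

test_that("projection collisions under strong boundary mismatch set the ordering flag", {
  m <- raster_ellipse_mask(ellipse(40, 30, 30, 20), 60, 80)
  # a grossly mis-fitted (shifted) ellipse: many consecutive vertices beyond
  # the mask project onto the same few boundary pixels at its tip, so the
  # projected points are no longer strictly cyclically ordered
  e_bad <- ellipse(65, 30, 30, 20)
  sub <- subdivide_boundary(e_bad, equilateral_side(30))
  expect_warning(co <- correspond_and_project(e_bad, sub, m), "ordered")
  expect_false(attr(co, "ordered"))
})

test_that("elastic deformation is exact for zero, rigid and affine boundary motion", {
  mesh <- small_mesh()
  bd <- mesh$vertices[mesh$boundary_vertex_ids, ]
  make_corr <- function(target) {
    co <- tibble::tibble(angle = mesh$subdivision$angles,
                         ex = bd[, 1], ey = bd[, 2],
                         px = target[, 1], py = target[, 2], distance = 0)
    class(co) <- c("boundary_correspondence", class(co))
    co
  }
  # zero displacement reproduces the generic mesh exactly
  d0 <- deform(mesh, make_corr(bd))
  expect_equal(d0$vertices, mesh$vertices, tolerance = 1e-12)
  # rigid translation carries every interior vertex along
  dt <- deform(mesh, make_corr(bd + matrix(c(4, -7), nrow(bd), 2, byrow = TRUE)))
  expect_equal(dt$vertices,
               mesh$vertices + matrix(c(4, -7), nrow(mesh$vertices), 2, byrow = TRUE),
               tolerance = 1e-8)
  # affine patch test: linear elements reproduce x -> Fx + t exactly
  Fm <- matrix(c(1.08, 0.05, -0.04, 0.93), 2)
  tv <- c(2, -3)
  da <- deform(mesh, make_corr(t(Fm %*% t(bd)) + matrix(tv, nrow(bd), 2, byrow = TRUE)))
  expected <- t(Fm %*% t(mesh$vertices)) +
    matrix(tv, nrow(mesh$vertices), 2, byrow = TRUE)
  expect_lt(max(abs(da$vertices - expected)), 1e-8)
  expect_equal(da$quality$n_folded, 0)
  expect_error(deform(mesh, make_corr(bd)[-1, ]), "every boundary vertex")
})

test_that("a single displaced boundary vertex produces a decaying displacement field", {
  mesh <- small_mesh()
  bd <- mesh$vertices[mesh$boundary_vertex_ids, ]
  target <- bd
  target[1, ] <- target[1, ] + c(3, 2)  # push one vertex outward
  co <- tibble::tibble(angle = mesh$subdivision$angles, ex = bd[, 1], ey = bd[, 2],
                       px = target[, 1], py = target[, 2], distance = 0)
  class(co) <- c("boundary_correspondence", class(co))
  d <- suppressWarnings(deform(mesh, co))
  mag <- sqrt(rowSums((d$vertices - mesh$vertices)^2))
  # BFS rings from the displaced vertex over mesh edges
  ed <- embryomesh:::mesh_edges(mesh)
  adj <- split(c(ed[, 2], ed[, 1]), c(ed[, 1], ed[, 2]))
  depth <- rep(NA_integer_, nrow(mesh$vertices))
  frontier <- mesh$boundary_vertex_ids[1]
  depth[frontier] <- 0L
  lvl <- 0L
  while (length(frontier)) {
    nxt <- unique(unlist(adj[as.character(frontier)]))
    nxt <- nxt[is.na(depth[nxt])]
    lvl <- lvl + 1L
    depth[nxt] <- lvl
    frontier <- nxt
  }
  prof <- tapply(mag, depth, mean)
  # ring-averaged displacement decays monotonically over the first rings
  expect_true(all(diff(prof[1:5]) < 0))
})

test_that("deforming and re-projecting boundary vertices is idempotent", {
  spec <- synthetic_spec(n_genes = 2, seed = 13)
  g <- generate_embryo(spec, 1)
  mask <- g$truth$mask
  fit <- fit_ellipse(extract_boundary(mask))
  mesh <- mesh_ellipse(average_ellipses(list(fit)), area_bound = 400)
  co <- correspond_and_project(fit, mesh$subdivision, mask)
  d <- deform(mesh, co)
  bd <- d$vertices[d$boundary_vertex_ids, ]
  again <- project_to_boundary(bd, mask)
  expect_equal(cbind(again$x, again$y), unname(bd))
  expect_equal(max(again$distance), 0)
})

test_that("deformed mesh sets share connectivity and report quality per image", {
  run <- planted_run()
  dm <- run$res$deformed
  expect_s3_class(dm, "deformed_mesh_set")
  nv <- vapply(dm$vertices, nrow, integer(1))
  expect_true(all(nv == nv[1]))
  expect_equal(nrow(dm$quality), length(dm$vertices))
  expect_true(all(dm$quality$ordered))
  expect_true(all(dm$quality$n_folded == 0))
})
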