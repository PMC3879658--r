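# unordered boundary pixel set: foreground pixels with a 4-connected
# background neighbor (image border counts as background); returned as pixel
# centers sorted lexicographically by (row, col) so that "first minimum"
# searches implement the documented tie-break
boundary_pixel_set <- function(mask) {
  mask <- as_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  nb_bg <- !pad[1:nr, 2:(nc + 1L)] | !pad[3:(nr + 2L), 2:(nc + 1L)] |
    !pad[2:(nr + 1L), 1:nc] | !pad[2:(nr + 1L), 3:(nc + 2L)]
  rc <- which(core & nb_bg, arr.ind = TRUE)
  rc <- rc[order(rc[, 1], rc[, 2]), , drop = FALSE]
  cbind(x = rc[, 2] - 0.5, y = rc[, 1] - 0.5)
}

#' Project points to the nearest boundary pixel of a mask
#'
#' Each input point is replaced by the boundary pixel center (foreground pixel
#' with a 4-connected background neighbor) at minimal Euclidean distance.
#' When several boundary pixels are equidistant the one with the lowest
#' (row, column) position wins. Pixel centers follow the `integer - 0.5`
#' convention used throughout the package.
#'
#' @param points A two-column matrix (or data frame with `x`, `y`) of query
#'   points.
#' @param mask A binary mask with a single foreground component.
#' @return A tibble with columns `x`, `y` (projected points) and `distance`.
#' @export
project_to_boundary <- function(points, mask) {
  pts <- as_xy(points)
  bp <- boundary_pixel_set(mask)
  if (!nrow(bp)) rlang::abort("mask has no boundary pixels")
  # squared distances, queries x boundary pixels; first min = lexicographic tie-break
  d2 <- outer(pts[, 1], bp[, 1], `-`)^2 + outer(pts[, 2], bp[, 2], `-`)^2
  idx <- max.col(-d2, ties.method = "first")
  tibble::tibble(x = bp[idx, 1], y = bp[idx, 2],
                 distance = sqrt(d2[cbind(seq_len(nrow(pts)), idx)]))
}

#' Carry subdivision angles to a fitted ellipse and project to the embryo
#'
#' Evaluates the generic mesh's boundary angles on the image's fitted ellipse
#' `E_j` and projects each resulting point to the nearest embryo boundary
#' pixel. The radial ordering of the projected points about the mask centroid
#' is checked; if boundary noise inverts the cyclic order the correspondence
#' is still returned, with `ordered = FALSE` recorded as a warning flag.
#'
#' @param ellipse_j The per-image fitted [ellipse()].
#' @param subdivision The generic ellipse's [subdivide_boundary()] result.
#' @param mask The image's binary foreground mask.
#' @param image_id Optional identifier stored on the result.
#' @return A `boundary_correspondence`: tibble with columns `angle`, `ex`,
#'   `ey` (point on `E_j`), `px`, `py` (projected boundary pixel) and
#'   `distance`; attributes `image_id` and `ordered`.
#' @export
correspond_and_project <- function(ellipse_j, subdivision, mask, image_id = NULL) {
  stopifnot(inherits(ellipse_j, "ellipse"), inherits(subdivision, "boundary_subdivision"))
  ep <- arc_point(ellipse_j, subdivision$angles)
  pr <- project_to_boundary(ep, mask)
  out <- tibble::tibble(angle = subdivision$angles, ex = ep[, 1], ey = ep[, 2],
                        px = pr$x, py = pr$y, distance = pr$distance)
  mask <- as_mask(mask)
  rc <- which(mask, arr.ind = TRUE)
  ctr <- c(mean(rc[, 2] - 0.5), mean(rc[, 1] - 0.5))
  pol <- atan2(out$py - ctr[2], out$px - ctr[1])
  d <- diff(c(pol, pol[1]))
  d <- (d + pi) %% (2 * pi) - pi  # wrapped angular steps
  ordered <- all(d > 0) || all(d < 0)
  if (!ordered) {
    rlang::warn("projected boundary vertices are not cyclically ordered; flagging correspondence")
  }
  attr(out, "image_id") <- image_id
  attr(out, "ordered") <- ordered
  class(out) <- c("boundary_correspondence", class(out))
  out
}

# element stiffness matrices for linear (P1) triangles, plane-stress
# elasticity; returns triplets for sparse assembly
elastic_stiffness_triplets <- function(vertices, triangles,
                                       young = 1, poisson = 0.3) {
  Dm <- young / (1 - poisson^2) *
    matrix(c(1, poisson, 0, poisson, 1, 0, 0, 0, (1 - poisson) / 2), 3, 3)
  nt <- nrow(triangles)
  ii <- jj <- integer(36L * nt)
  vv <- numeric(36L * nt)
  pos <- 0L
  for (t in seq_len(nt)) {
    id <- triangles[t, ]
    p <- vertices[id, , drop = FALSE]
    b <- c(p[2, 2] - p[3, 2], p[3, 2] - p[1, 2], p[1, 2] - p[2, 2])
    g <- c(p[3, 1] - p[2, 1], p[1, 1] - p[3, 1], p[2, 1] - p[1, 1])
    area2 <- (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
      (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])
    B <- matrix(0, 3, 6)
    B[1, c(1, 3, 5)] <- b
    B[2, c(2, 4, 6)] <- g
    B[3, c(1, 3, 5)] <- g
    B[3, c(2, 4, 6)] <- b
    B <- B / area2
    Ke <- (abs(area2) / 2) * t(B) %*% Dm %*% B
    dof <- as.vector(rbind(2L * id - 1L, 2L * id))
    idx <- pos + seq_len(36L)
    ii[idx] <- rep(dof, times = 6L)
    jj[idx] <- rep(dof, each = 6L)
    vv[idx] <- as.vector(Ke)
    pos <- pos + 36L
  }
  list(i = ii, j = jj, v = vv)
}

#' Deform the generic mesh onto one embryo
#'
#' The boundary vertices of the generic mesh take the projected coordinates
#' exactly (Dirichlet constraints, imposed by system reduction); interior
#' vertex displacements solve the plane-stress linear-elasticity problem
#' (linear triangle elements, Young's modulus 1, Poisson ratio 0.3) on the
#' generic mesh. Linear elements reproduce affine displacement fields exactly,
#' so rigid and affine boundary motions carry through to the interior without
#' distortion; general boundary displacements decay smoothly with distance
#' from the boundary.
#'
#' @param mesh The generic `tri_mesh`.
#' @param correspondence A [correspond_and_project()] result covering all
#'   boundary vertices (in subdivision order).
#' @param strict If `TRUE`, abort when the deformed mesh contains folded
#'   (negatively oriented) triangles; default reports them in the quality
#'   field and continues.
#' @return A `deformed_mesh`: list with `vertices` (deformed coordinates,
#'   same row order as `mesh$vertices`), shared `triangles`, and `quality`
#'   (one-row tibble: `min_angle`, `min_signed_area`, `n_folded`).
#' @export
deform <- function(mesh, correspondence, strict = FALSE) {
  stopifnot(inherits(mesh, "tri_mesh"))
  bid <- mesh$boundary_vertex_ids
  if (nrow(correspondence) != length(bid)) {
    rlang::abort("correspondence must cover every boundary vertex of the mesh")
  }
  V <- mesh$vertices
  nv <- nrow(V)
  target <- cbind(correspondence$px, correspondence$py)
  ub <- target - V[bid, , drop = FALSE]
  if (all(abs(ub) < 1e-14)) {
    u <- matrix(0, nv, 2)
  } else {
    tri <- mesh$triangles
    tp <- elastic_stiffness_triplets(V, tri)
    K <- Matrix::sparseMatrix(i = tp$i, j = tp$j, x = tp$v, dims = c(2L * nv, 2L * nv))
    fixed_dof <- sort(c(2L * bid - 1L, 2L * bid))
    free_dof <- setdiff(seq_len(2L * nv), fixed_dof)
    ufix <- numeric(2L * nv)
    ufix[2L * bid - 1L] <- ub[, 1]
    ufix[2L * bid] <- ub[, 2]
    rhs <- -K[free_dof, fixed_dof, drop = FALSE] %*% ufix[fixed_dof]
    Kff <- K[free_dof, free_dof, drop = FALSE]
    sol <- tryCatch(Matrix::solve(Kff, rhs),
                    error = function(e) rlang::abort(
                      paste("elastic system is singular:", conditionMessage(e))))
    u <- ufix
    u[free_dof] <- as.numeric(sol)
    u <- matrix(u, ncol = 2, byrow = TRUE)
  }
  Vd <- V + u
  Vd[bid, ] <- target  # exact at constrained vertices
  q <- triangle_quality(Vd, mesh$triangles)
  folded <- sum(q$signed_area <= 0)
  if (folded > 0) {
    msg <- sprintf("deformed mesh contains %d folded triangle(s)", folded)
    if (strict) rlang::abort(msg) else rlang::warn(msg)
  }
  structure(list(vertices = Vd, triangles = mesh$triangles,
                 boundary_vertex_ids = bid,
                 quality = tibble::tibble(min_angle = min(q$min_angle),
                                          min_signed_area = min(q$signed_area),
                                          n_folded = folded)),
            class = "deformed_mesh")
}

#' Deform the generic mesh onto every image of a set
#'
#' Applies [correspond_and_project()] and [deform()] per image. All deformed
#' meshes share the generic mesh's connectivity (the triangle list is stored
#' once); only vertex coordinates differ.
#'
#' @param mesh The generic `tri_mesh` (must carry its `subdivision`, as built
#'   by [mesh_ellipse()]).
#' @param ellipses List of per-image fitted [ellipse()] objects.
#' @param masks List of per-image binary masks (same length/order).
#' @param ids Optional image identifiers.
#' @param strict Passed to [deform()].
#' @return A `deformed_mesh_set`: list with `triangles` (shared), `vertices`
#'   (list of per-image coordinate matrices), `quality` (tibble, one row per
#'   image) and `correspondences`.
#' @export
deform_mesh_set <- function(mesh, ellipses, masks, ids = NULL, strict = FALSE) {
  stopifnot(length(ellipses) == length(masks))
  if (is.null(mesh$subdivision)) {
    rlang::abort("mesh must carry its boundary subdivision (use mesh_ellipse())")
  }
  if (is.null(ids)) ids <- names(masks) %||% as.character(seq_along(masks))
  cors <- purrr::pmap(list(ellipses, masks, ids), function(e, m, id) {
    correspond_and_project(e, mesh$subdivision, m, image_id = id)
  })
  defs <- purrr::map(cors, function(co) deform(mesh, co, strict = strict))
  quality <- purrr::map2_dfr(defs, ids, function(d, id) {
    dplyr::bind_cols(tibble::tibble(image_id = id), d$quality)
  })
  quality$ordered <- vapply(cors, function(co) isTRUE(attr(co, "ordered")), logical(1))
  structure(list(triangles = mesh$triangles,
                 vertices = purrr::map(defs, "vertices"),
                 ids = ids, quality = quality,
                 correspondences = cors,
                 boundary_vertex_ids = mesh$boundary_vertex_ids),
            class = "deformed_mesh_set")
}

#' @export
print.deformed_mesh_set <- function(x, ...) {
  cat(sprintf("<deformed_mesh_set> %d images, %d shared triangles, %d vertices each\n",
              length(x$vertices), nrow(x$triangles), nrow(x$vertices[[1]])))
  if (any(x$quality$n_folded > 0)) {
    cat(sprintf("  %d image(s) with folded triangles\n", sum(x$quality$n_folded > 0)))
  }
  invisible(x)
}
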