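# assign pixel centers to mesh triangles: a pixel belongs to the triangle
# containing its center; pixels exactly on a shared edge go to the
# lowest-index incident triangle (triangles are scanned in increasing index
# and only unassigned pixels are claimed). Returns an H x W integer matrix,
# 0 = outside the mesh.
pixel_triangle_map <- function(vertices, triangles, image_size) {
  H <- image_size[1]; W <- image_size[2]
  assign <- matrix(0L, H, W)
  eps <- 1e-9
  for (t in seq_len(nrow(triangles))) {
    p <- vertices[triangles[t, ], , drop = FALSE]
    cmin <- max(1L, floor(min(p[, 1]) + 0.5) + 1L - 1L)
    cmax <- min(W, ceiling(max(p[, 1]) + 0.5))
    rmin <- max(1L, floor(min(p[, 2]) + 0.5) + 1L - 1L)
    rmax <- min(H, ceiling(max(p[, 2]) + 0.5))
    if (cmin > cmax || rmin > rmax) next
    cols <- cmin:cmax; rows <- rmin:rmax
    px <- rep(cols - 0.5, each = length(rows))
    py <- rep(rows - 0.5, times = length(cols))
    d <- (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
      (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])
    l1 <- ((p[2, 2] - p[3, 2]) * (px - p[3, 1]) + (p[3, 1] - p[2, 1]) * (py - p[3, 2])) / d
    l2 <- ((p[3, 2] - p[1, 2]) * (px - p[3, 1]) + (p[1, 1] - p[3, 1]) * (py - p[3, 2])) / d
    l3 <- 1 - l1 - l2
    inside <- l1 >= -eps & l2 >= -eps & l3 >= -eps
    if (!any(inside)) next
    rr <- rep(rows, times = length(cols))[inside]
    cc <- rep(cols, each = length(rows))[inside]
    idx <- cbind(rr, cc)
    unclaimed <- assign[idx] == 0L
    assign[idx[unclaimed, , drop = FALSE]] <- t
  }
  assign
}

#' Median gray-level intensity of each mesh element
#'
#' Assigns every pixel whose center lies inside the deformed mesh to exactly
#' one triangle (lowest-index triangle on shared edges) and returns the
#' median intensity per triangle. A triangle covering no pixel center gets
#' the value 0 and is flagged in the `empty_elements` attribute.
#'
#' @param image H x W grayscale matrix (values in `[0, 255]`).
#' @param vertices Deformed vertex coordinates (V x 2).
#' @param triangles Shared triangle index list (T x 3).
#' @return Numeric vector of length T (one median per element), with
#'   attributes `empty_elements` (integer vector) and `n_pixels` (per-element
#'   pixel counts).
#' @export
element_medians <- function(image, vertices, triangles) {
  stopifnot(is.matrix(image))
  pmap <- pixel_triangle_map(vertices, triangles, dim(image))
  nt <- nrow(triangles)
  med <- numeric(nt)
  counts <- integer(nt)
  sel <- pmap > 0L
  vals <- image[sel]
  ids <- pmap[sel]
  agg <- vapply(split(vals, ids), stats::median, numeric(1))
  present <- as.integer(names(agg))
  med[present] <- agg
  counts <- as.integer(table(factor(ids, levels = seq_len(nt))))
  empty <- which(counts == 0L)
  if (length(empty)) {
    rlang::warn(sprintf("%d mesh element(s) cover no pixel center; set to 0", length(empty)))
  }
  attr(med, "empty_elements") <- empty
  attr(med, "n_pixels") <- counts
  med
}

#' Assemble the genes x mesh-elements expression matrix
#'
#' One row per gene-image table row (several images of one gene stay separate
#' rows), one column per mesh element in the fixed element numbering of the
#' generic mesh. Entries are median element intensities and hence
#' nonnegative.
#'
#' @param table Tibble with columns `gene_id` and `image_id`; row order is
#'   preserved in the matrix.
#' @param images Named or ordered list of H x W image matrices (one per table
#'   row, matched by `image_id` when names are present, else by position).
#' @param deformed A `deformed_mesh_set` from [deform_mesh_set()] whose order
#'   matches the images.
#' @return An `expression_matrix`: numeric matrix (rownames = `image_id`,
#'   attribute `gene_ids`), with `tidy()` support.
#' @export
assemble_matrix <- function(table, images, deformed) {
  stopifnot(inherits(deformed, "deformed_mesh_set"))
  if (nrow(table) != length(images) || nrow(table) != length(deformed$vertices)) {
    rlang::abort("table rows, images and deformed meshes must correspond 1:1")
  }
  rows <- purrr::map(seq_len(nrow(table)), function(i) {
    element_medians(images[[i]], deformed$vertices[[i]], deformed$triangles)
  })
  A <- do.call(rbind, purrr::map(rows, as.numeric))
  rownames(A) <- table$image_id
  colnames(A) <- paste0("el", seq_len(ncol(A)))
  attr(A, "gene_ids") <- table$gene_id
  attr(A, "empty_elements") <- purrr::map(rows, attr, "empty_elements")
  class(A) <- c("expression_matrix", class(A))
  A
}

#' Long-format view of an expression matrix
#'
#' @param x An `expression_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `image_id`, `gene_id`, `element`, `intensity`.
#' @method tidy expression_matrix
#' @export
tidy.expression_matrix <- function(x, ...) {
  gene <- attr(x, "gene_ids")
  tibble::tibble(image_id = rep(rownames(x), times = ncol(x)),
                 gene_id = rep(gene, times = ncol(x)),
                 element = rep(seq_len(ncol(x)), each = nrow(x)),
                 intensity = as.numeric(unclass(x)))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d rows (gene images) x %d mesh elements\n",
              nrow(x), ncol(x)))
  invisible(x)
}
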