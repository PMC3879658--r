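#' Plot a mesh, optionally colored by cluster
#'
#' Draws the triangulation of the average ellipse with ggplot2; when `fill`
#' is given, elements sharing a cluster share a color and the legend lists
#' one entry per distinct cluster (the style of fate-map-like cluster maps).
#'
#' @param object A `tri_mesh`.
#' @param fill Optional per-element cluster labels (length = number of
#'   triangles).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tri_mesh
#' @export
autoplot.tri_mesh <- function(object, fill = NULL, ...) {
  tri <- object$triangles
  nt <- nrow(tri)
  if (!is.null(fill) && length(fill) != nt) {
    rlang::abort("fill must supply one cluster label per mesh element")
  }
  df <- tibble::tibble(
    element = rep(seq_len(nt), each = 3L),
    x = object$vertices[t(tri), 1],
    y = object$vertices[t(tri), 2])
  if (is.null(fill)) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                          group = .data$element)) +
      ggplot2::geom_polygon(fill = "grey90", color = "grey30", linewidth = 0.2)
  } else {
    df$cluster <- factor(rep(fill, each = 3L))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                          group = .data$element,
                                          fill = .data$cluster)) +
      ggplot2::geom_polygon(color = "grey25", linewidth = 0.15) +
      ggplot2::labs(fill = "cluster")
  }
  p + ggplot2::scale_y_reverse() + ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Render element clusters on the average-ellipse mesh
#'
#' Builds both a ggplot (for interactive use) and a deterministic raster
#' image in which every pixel inside the mesh carries its element's cluster
#' color. The raster (written by [write_rendering()]) is byte-reproducible,
#' which keeps pipeline manifests checksum-stable.
#'
#' @param mesh A `tri_mesh`.
#' @param labels Integer cluster label per mesh element.
#' @param image_size `c(height, width)` of the raster; defaults to the mesh
#'   bounding box plus a margin.
#' @return A `cluster_rendering`: list with `plot` (ggplot), `raster`
#'   (H x W x 3 array in `[0, 1]`), `labels` and `palette` (one color per
#'   distinct cluster).
#' @export
render_clusters <- function(mesh, labels, image_size = NULL) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (length(labels) != nrow(mesh$triangles)) {
    rlang::abort(sprintf("got %d labels for %d mesh elements",
                         length(labels), nrow(mesh$triangles)))
  }
  if (is.null(image_size)) {
    image_size <- c(ceiling(max(mesh$vertices[, 2]) + 5),
                    ceiling(max(mesh$vertices[, 1]) + 5))
  }
  lv <- sort(unique(labels))
  palette <- grDevices::hcl(h = seq(15, 375, length.out = length(lv) + 1L)[seq_along(lv)],
                            c = 80, l = 60)
  pmap <- pixel_triangle_map(mesh$vertices, mesh$triangles, image_size)
  H <- image_size[1]; W <- image_size[2]
  raster <- array(1, dim = c(H, W, 3))
  rgb <- grDevices::col2rgb(palette) / 255
  sel <- pmap > 0L
  cl_idx <- match(labels[pmap[sel]], lv)
  for (ch in 1:3) {
    plane <- raster[, , ch]
    plane[sel] <- rgb[ch, cl_idx]
    raster[, , ch] <- plane
  }
  structure(list(plot = autoplot.tri_mesh(mesh, fill = labels),
                 raster = raster, labels = labels,
                 palette = stats::setNames(palette, lv)),
            class = "cluster_rendering")
}

#' Write a cluster rendering to PNG
#'
#' @param rendering A [render_clusters()] result.
#' @param path Output PNG path.
#' @export
write_rendering <- function(rendering, path) {
  png::writePNG(rendering$raster, path)
  invisible(path)
}

#' @export
print.cluster_rendering <- function(x, ...) {
  cat(sprintf("<cluster_rendering> %d elements, %d clusters\n",
              length(x$labels), length(x$palette)))
  invisible(x)
}

#' Spatial contiguity of element clusters
#'
#' Fraction of element-adjacency edges (triangles sharing an edge) whose two
#' elements carry the same cluster label. Values near 1 indicate spatially
#' contiguous cluster domains.
#'
#' @param mesh A `tri_mesh`.
#' @param labels Per-element cluster labels.
#' @return Scalar in `[0, 1]`.
#' @export
cluster_contiguity <- function(mesh, labels) {
  adj <- element_adjacency(mesh)
  if (!nrow(adj)) return(NA_real_)
  mean(labels[adj[, 1]] == labels[adj[, 2]])
}
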