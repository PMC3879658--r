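# -- images ------------------------------------------------------------------

#' Read a grayscale image as a 0-255 matrix
#'
#' PNG images are read with the png package; multi-channel images are
#' averaged to gray. Values are scaled to `[0, 255]`.
#'
#' @param path PNG file path.
#' @return H x W numeric matrix.
#' @export
read_gray_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE], c(1, 2), mean)
  a * 255
}

#' Write a 0-255 matrix as a grayscale PNG
#'
#' @param image H x W numeric matrix, values in `[0, 255]`.
#' @param path Output path.
#' @export
write_gray_png <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

# a simple foreground mask for standardized embryo images: pixels above a
# gray threshold, used when no explicit mask images are provided
threshold_mask <- function(image, threshold = 1) image > threshold

# -- ellipse -----------------------------------------------------------------

#' Write ellipse parameters to JSON
#'
#' Keys: `cx`, `cy`, `a`, `b`, `theta`; a list of ellipses becomes a JSON
#' array.
#'
#' @param x An [ellipse()] or list of them (optionally named).
#' @param path Output path.
#' @export
write_ellipse_json <- function(x, path) {
  to_rec <- function(e) list(cx = e$cx, cy = e$cy, a = e$a, b = e$b, theta = e$theta)
  obj <- if (inherits(x, "ellipse")) to_rec(x) else purrr::map(x, to_rec)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ellipse parameters from JSON
#'
#' @param path JSON written by [write_ellipse_json()].
#' @return An [ellipse()] or list of them.
#' @export
read_ellipse_json <- function(path) {
  obj <- jsonlite::read_json(path)
  from_rec <- function(r) ellipse(r$cx, r$cy, r$a, r$b, r$theta)
  if (!is.null(obj$cx)) from_rec(obj) else purrr::map(obj, from_rec)
}

# -- mesh --------------------------------------------------------------------

#' Write a mesh as CSV files plus a JSON bundle
#'
#' Writes `vertices.csv` (id, x, y), `triangles.csv` (id, v1, v2, v3),
#' `boundary.csv` (id) and `mesh.json` (everything, plus bounds). Indices in
#' the files are 0-based, as noted in each file's header comment line.
#'
#' @param mesh A `tri_mesh`.
#' @param dir Output directory (created if needed).
#' @export
write_mesh <- function(mesh, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vt <- tibble::tibble(id = seq_len(nrow(mesh$vertices)) - 1L,
                       x = mesh$vertices[, 1], y = mesh$vertices[, 2])
  tr <- tibble::tibble(id = seq_len(nrow(mesh$triangles)) - 1L,
                       v1 = mesh$triangles[, 1] - 1L,
                       v2 = mesh$triangles[, 2] - 1L,
                       v3 = mesh$triangles[, 3] - 1L)
  bd <- tibble::tibble(id = mesh$boundary_vertex_ids - 1L)
  write_csv_commented(vt, file.path(dir, "vertices.csv"), "# vertex ids are 0-based")
  write_csv_commented(tr, file.path(dir, "triangles.csv"), "# vertex ids are 0-based")
  write_csv_commented(bd, file.path(dir, "boundary.csv"), "# vertex ids are 0-based")
  jsonlite::write_json(
    list(vertices = unname(split(mesh$vertices, row(mesh$vertices))),
         triangles = unname(split(mesh$triangles - 1L, row(mesh$triangles))),
         boundary_vertex_ids = mesh$boundary_vertex_ids - 1L,
         area_bound = mesh$area_bound, angle_bound = mesh$angle_bound,
         index_base = 0),
    file.path(dir, "mesh.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

write_csv_commented <- function(df, path, comment) {
  con <- file(path, "w")
  writeLines(comment, con)
  close(con)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a mesh written by [write_mesh()]
#'
#' @param dir Directory containing `mesh.json`.
#' @return A `tri_mesh`.
#' @export
read_mesh <- function(dir) {
  obj <- jsonlite::read_json(file.path(dir, "mesh.json"), simplifyVector = TRUE)
  to_mat <- function(x) if (is.matrix(x)) x else do.call(rbind, x)
  tri <- to_mat(obj$triangles) + 1
  storage.mode(tri) <- "integer"
  vt <- to_mat(obj$vertices)
  dimnames(vt) <- NULL; dimnames(tri) <- NULL
  structure(list(vertices = vt, triangles = tri,
                 boundary_vertex_ids = as.integer(obj$boundary_vertex_ids) + 1L,
                 area_bound = obj$area_bound, angle_bound = obj$angle_bound),
            class = "tri_mesh")
}

# -- deformed meshes ---------------------------------------------------------

#' Write per-image deformed vertex coordinates and quality reports
#'
#' Vertices go to one long CSV (`image_id`, `vertex_id` 0-based, `x`, `y`);
#' the per-image quality report to JSON.
#'
#' @param deformed A `deformed_mesh_set`.
#' @param dir Output directory.
#' @export
write_deformed_set <- function(deformed, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- purrr::map2_dfr(deformed$vertices, deformed$ids, function(v, id) {
    tibble::tibble(image_id = id, vertex_id = seq_len(nrow(v)) - 1L,
                   x = v[, 1], y = v[, 2])
  })
  readr::write_csv(long, file.path(dir, "deformed_vertices.csv"))
  jsonlite::write_json(deformed$quality, file.path(dir, "quality.json"),
                       digits = NA, dataframe = "rows")
  invisible(dir)
}

# -- expression matrix -------------------------------------------------------

#' Write an expression matrix as CSV
#'
#' Header row carries element ids, the first column the row (image) ids; a
#' second column carries the gene ids attached to each row.
#'
#' @param A An `expression_matrix`.
#' @param path Output CSV path.
#' @export
write_expression_csv <- function(A, path) {
  df <- tibble::as_tibble(unclass(A))
  df <- dplyr::bind_cols(tibble::tibble(image_id = rownames(A),
                                        gene_id = attr(A, "gene_ids")), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' Read an expression matrix written by [write_expression_csv()]
#'
#' @param path CSV path.
#' @return An `expression_matrix`.
#' @export
read_expression_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  A <- as.matrix(df[, !(names(df) %in% c("image_id", "gene_id")), drop = FALSE])
  rownames(A) <- df$image_id
  attr(A, "gene_ids") <- df$gene_id
  class(A) <- c("expression_matrix", class(A))
  A
}

# -- model -------------------------------------------------------------------

#' Persist a fitted co-cluster model as a CSV/JSON bundle
#'
#' Writes `P.csv`, `Q.csv` and `meta.json` (c, seed, trace, convergence).
#'
#' @param model A `cocluster_model`.
#' @param dir Output directory.
#' @export
write_cocluster_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tibble::as_tibble(model$P, .name_repair = ~ paste0("k", seq_len(model$c))),
                   file.path(dir, "P.csv"))
  readr::write_csv(tibble::as_tibble(model$Q, .name_repair = ~ paste0("k", seq_len(model$c))),
                   file.path(dir, "Q.csv"))
  jsonlite::write_json(list(c = model$c, seed = model$seed, loglik = model$loglik,
                            loglik_trace = model$loglik_trace,
                            converged = model$converged,
                            best_restart = model$best_restart,
                            row_ids = model$row_ids, col_ids = model$col_ids),
                       file.path(dir, "meta.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Write hard assignments as TSV
#'
#' Two files: `gene_clusters.tsv` (`id`, `cluster`) and
#' `element_clusters.tsv`.
#'
#' @param assignment A `cocluster_assignment`.
#' @param dir Output directory.
#' @export
write_assignments <- function(assignment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(assignment$rows, file.path(dir, "gene_clusters.tsv"))
  readr::write_tsv(assignment$columns, file.path(dir, "element_clusters.tsv"))
  invisible(dir)
}

#' Read a two-column annotation table
#'
#' Accepts a plain 2-column TSV (`gene_id`, `term_id`, with or without
#' header) or a GAF-like file whose second and fifth columns hold the gene
#' and term ids.
#'
#' @param path TSV path.
#' @return Tibble `gene_id`, `term_id`.
#' @export
read_annotations <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  ncol1 <- length(strsplit(first, "\t")[[1]])
  if (ncol1 >= 15) {  # GAF
    df <- readr::read_tsv(path, comment = "!", col_names = FALSE, show_col_types = FALSE)
    return(tibble::tibble(gene_id = df[[2]], term_id = df[[5]]))
  }
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_names = !grepl("gene", first, ignore.case = TRUE) == FALSE)
  if (!all(c("gene_id", "term_id") %in% names(df))) {
    df <- readr::read_tsv(path, col_names = c("gene_id", "term_id"),
                          show_col_types = FALSE)
  }
  tibble::tibble(gene_id = as.character(df$gene_id), term_id = as.character(df$term_id))
}
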