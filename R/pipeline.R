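#' Configure a full pipeline run
#'
#' Inputs may be given in memory (`images`, `table`, optionally `masks`) or
#' as a directory containing PNG images and a `gene_image_table.tsv`
#' (`gene_id`, `image_path`). Exactly one of `area_bound` and
#' `target_elements` must be set.
#'
#' @param out_dir Output directory for all artifacts.
#' @param n_clusters Number of co-clusters `c`.
#' @param images List of H x W gray matrices (0-255), or `NULL` with
#'   `input_dir`.
#' @param table Tibble with `gene_id` and `image_id` (in-memory input) or
#'   `gene_id` and `image_path` (directory input).
#' @param masks Optional list of binary masks; by default foreground is taken
#'   as pixels above `mask_threshold` gray levels.
#' @param input_dir Directory holding `gene_image_table.tsv` and images.
#' @param annotations Optional annotation tibble (`gene_id`, `term_id`) or
#'   TSV path, enabling the enrichment stage.
#' @param area_bound Maximum triangle area (square pixels).
#' @param target_elements Desired mesh element count (alternative).
#' @param angle_bound Minimum interior angle bound, degrees (default 25).
#' @param seed Integer seed for the co-clustering restarts.
#' @param n_restarts,tol,max_iter Co-clustering fit controls.
#' @param mask_threshold Gray threshold for the default foreground masks.
#' @param enrichment_threshold Significance threshold for enrichment.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, n_clusters,
                            images = NULL, table = NULL, masks = NULL,
                            input_dir = NULL, annotations = NULL,
                            area_bound = NULL, target_elements = NULL,
                            angle_bound = 25, seed = 1,
                            n_restarts = 5, tol = 1e-8, max_iter = 500,
                            mask_threshold = 1, enrichment_threshold = 0.001) {
  if (is.null(area_bound) == is.null(target_elements)) {
    rlang::abort("set exactly one of area_bound and target_elements")
  }
  if (is.null(input_dir) && (is.null(images) || is.null(table))) {
    rlang::abort("provide either input_dir or in-memory images + table")
  }
  if (!is.null(area_bound) && area_bound <= 0) rlang::abort("area_bound must be positive")
  if (angle_bound > 25 || angle_bound <= 0) rlang::abort("angle_bound must be in (0, 25]")
  if (n_clusters < 1) rlang::abort("n_clusters must be >= 1")
  structure(list(out_dir = out_dir, n_clusters = as.integer(n_clusters),
                 images = images, table = table, masks = masks,
                 input_dir = input_dir, annotations = annotations,
                 area_bound = area_bound, target_elements = target_elements,
                 angle_bound = angle_bound, seed = as.integer(seed),
                 n_restarts = n_restarts, tol = tol, max_iter = max_iter,
                 mask_threshold = mask_threshold,
                 enrichment_threshold = enrichment_threshold),
            class = "pipeline_config")
}

#' Run the full image-to-co-clusters pipeline
#'
#' Stages: load images -> foreground masks -> per-image ellipse fits ->
#' average ellipse -> boundary subdivision and quality mesh -> per-image
#' elastic deformation -> expression matrix -> co-clustering -> optional
#' enrichment -> cluster rendering. Every intermediate artifact is written
#' under `config$out_dir` together with `manifest.json` recording the
#' configuration, package version, per-stage warnings and an MD5 checksum of
#' every artifact file. Reruns with the same configuration reproduce
#' identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) a list with the in-memory results of each stage and
#'   the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- list()
  stage <- function(name, expr) {
    ws <- character(0)
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        rlang::abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
      }),
      warning = function(w) {
        ws <<- c(ws, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (length(ws)) warnings_log[[name]] <<- ws
    res
  }

  inp <- stage("load", load_pipeline_inputs(config))
  masks <- config$masks %||%
    purrr::map(inp$images, threshold_mask, threshold = config$mask_threshold)

  fits <- stage("fit-ellipses", fit_embryo_ellipses(masks, ids = inp$table$image_id))
  write_ellipse_json(c(fits$ellipses, list(average = fits$average)),
                     file.path(out, "ellipses.json"))

  mesh <- stage("mesh", mesh_ellipse(fits$average,
                                     area_bound = config$area_bound,
                                     target_elements = config$target_elements,
                                     angle_bound = config$angle_bound))
  write_mesh(mesh, file.path(out, "mesh"))

  deformed <- stage("deform", deform_mesh_set(mesh, fits$ellipses, masks,
                                              ids = inp$table$image_id))
  write_deformed_set(deformed, file.path(out, "deformed"))

  A <- stage("matrix", assemble_matrix(inp$table, inp$images, deformed))
  write_expression_csv(A, file.path(out, "expression_matrix.csv"))

  model <- stage("cocluster", cocluster(A, c = config$n_clusters,
                                        seed = config$seed, tol = config$tol,
                                        max_iter = config$max_iter,
                                        n_restarts = config$n_restarts))
  write_cocluster_model(model, file.path(out, "model"))
  assignment <- hard_assignments(model)
  write_assignments(assignment, file.path(out, "assignments"))

  enrichment <- NULL
  if (!is.null(config$annotations)) {
    ann <- if (is.character(config$annotations)) read_annotations(config$annotations)
           else config$annotations
    enrichment <- stage("enrich", enrich_clusters(assignment, ann,
                                                  threshold = config$enrichment_threshold))
    readr::write_tsv(tibble::as_tibble(enrichment), file.path(out, "enrichment.tsv"))
  }

  rendering <- stage("render", render_clusters(mesh, assignment$columns$cluster))
  write_rendering(rendering, file.path(out, "element_clusters.png"))

  manifest <- build_manifest(config, out, warnings_log,
                             glance.tri_mesh(mesh), glance.cocluster_model(model))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(inputs = inp, masks = masks, fits = fits, mesh = mesh,
                 deformed = deformed, matrix = A, model = model,
                 assignment = assignment, enrichment = enrichment,
                 rendering = rendering, manifest = manifest))
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$input_dir)) {
    tab <- readr::read_tsv(file.path(config$input_dir, "gene_image_table.tsv"),
                           show_col_types = FALSE)
    if (!all(c("gene_id", "image_path") %in% names(tab))) {
      rlang::abort("gene_image_table.tsv must have columns gene_id, image_path")
    }
    paths <- tab$image_path
    rel <- !file.exists(paths)
    paths[rel] <- file.path(config$input_dir, basename(paths[rel]))
    missing <- !file.exists(paths)
    if (any(missing)) {
      rlang::abort(paste("missing image file(s):", paste(paths[missing], collapse = ", ")))
    }
    images <- purrr::map(paths, read_gray_png)
    if (!"image_id" %in% names(tab)) {
      tab$image_id <- sub("[.]png$", "", basename(paths))
    }
    return(list(images = images, table = tibble::as_tibble(tab)))
  }
  tab <- tibble::as_tibble(config$table)
  if (!"image_id" %in% names(tab)) {
    tab$image_id <- sprintf("img%03d", seq_len(nrow(tab)))
  }
  if (nrow(tab) != length(config$images)) {
    rlang::abort("table must have one row per image")
  }
  list(images = config$images, table = tab)
}

build_manifest <- function(config, out, warnings_log, mesh_summary, model_summary) {
  files <- sort(setdiff(list.files(out, recursive = TRUE), "manifest.json"))
  sums <- tools::md5sum(file.path(out, files))
  cfg <- config
  cfg$images <- NULL; cfg$masks <- NULL; cfg$table <- NULL; cfg$annotations <- NULL
  list(package = "embryomesh",
       version = as.character(utils::packageVersion("embryomesh")),
       config = unclass(cfg),
       elastic_model = list(type = "plane-stress linear elasticity, P1 triangles",
                            young = 1, poisson = 0.3),
       pixel_convention = "pixel (row r, col c) center at (c - 0.5, r - 0.5)",
       mesh = as.list(mesh_summary),
       cocluster = as.list(model_summary),
       warnings = warnings_log,
       checksums = as.list(stats::setNames(as.character(sums), files)))
}
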