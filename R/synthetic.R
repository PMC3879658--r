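#' Specify a synthetic embryo image set
#'
#' Describes a set of embryo-like grayscale images with known ground truth:
#' each image's foreground is the base ellipse with a smooth, star-shaped
#' radial boundary perturbation (a low-order Fourier series in polar angle,
#' at most 5 harmonics, so the boundary never self-intersects), and gene
#' expression is painted into rectangular domains of the ellipse-normalized
#' (anterior-posterior `u`, dorsal-ventral `v`) frame, so the same domain maps
#' consistently across perturbed embryos. Defaults emulate standardized,
#' laterally oriented early-stage embryo images: a roughly 2:1 ellipse in a
#' 320 x 160 px frame, a few pixels of shape variation, strong expression
#' domains over a faint background with mild pixel noise.
#'
#' @param n_genes Number of genes (>= 1).
#' @param image_size `c(height, width)` in pixels.
#' @param base_ellipse The shared base [ellipse()].
#' @param boundary_noise_amplitude Maximum radial boundary perturbation,
#'   pixels. Must stay below 90% of the semi-minor axis so the star-shaped
#'   boundary cannot self-intersect.
#' @param domain_layout Tibble with one row per expression domain: columns
#'   `domain` (integer id), `u_min`, `u_max`, `v_min`, `v_max` (bounds in the
#'   ellipse-normalized frame, where the embryo is the unit disc), `level`
#'   (gray value in `[0, 255]`) and `genes` (list-column of member gene
#'   indices). `NULL` selects a default three-domain layout (anterior,
#'   mid-ventral, posterior bands) splitting the genes into three groups.
#' @param background_level Gray value of unexpressed embryo tissue.
#' @param pixel_noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param seed Integer seed; all images are reproducible from it.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 12,
                           image_size = c(160, 320),
                           base_ellipse = ellipse(160, 80, 140, 60),
                           boundary_noise_amplitude = 4,
                           domain_layout = NULL,
                           background_level = 20,
                           pixel_noise_sd = 6,
                           seed = 42) {
  stopifnot(n_genes >= 1, length(image_size) == 2, inherits(base_ellipse, "ellipse"))
  if (boundary_noise_amplitude < 0 ||
      boundary_noise_amplitude >= 0.9 * base_ellipse$b) {
    rlang::abort("boundary_noise_amplitude must be in [0, 0.9 * semi-minor axis): larger perturbations can self-intersect")
  }
  if (is.null(domain_layout)) domain_layout <- default_domain_layout(n_genes)
  check_domain_layout(domain_layout, n_genes)
  structure(list(n_genes = as.integer(n_genes), image_size = as.integer(image_size),
                 base_ellipse = base_ellipse,
                 boundary_noise_amplitude = boundary_noise_amplitude,
                 domain_layout = domain_layout,
                 background_level = background_level,
                 pixel_noise_sd = pixel_noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# three well-separated bands along the A/P axis, one ventral: genes split
# into three near-equal groups, one group per domain
default_domain_layout <- function(n_genes) {
  grp <- rep(1:3, length.out = n_genes)
  groups <- lapply(1:3, function(k) which(grp == k))
  tibble::tibble(
    domain = 1:3,
    u_min = c(-0.95, -0.30, 0.45), u_max = c(-0.45, 0.30, 0.95),
    v_min = c(-0.9, 0.0, -0.9), v_max = c(0.9, 0.9, 0.9),
    level = c(210, 200, 220),
    genes = unname(groups))
}

check_domain_layout <- function(layout, n_genes) {
  need <- c("domain", "u_min", "u_max", "v_min", "v_max", "level", "genes")
  if (!all(need %in% names(layout))) {
    rlang::abort(paste("domain_layout must have columns:", paste(need, collapse = ", ")))
  }
  if (any(layout$level < 0 | layout$level > 255)) {
    rlang::abort("expression levels must lie in [0, 255]")
  }
  g <- unlist(layout$genes)
  if (length(g) && (any(g < 1) || any(g > n_genes))) {
    rlang::abort("domain gene indices must lie in 1..n_genes")
  }
  invisible(TRUE)
}

# deterministic per-image seed derived from (spec seed, image index)
image_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 10007 + as.numeric(index) * 97) %% 2147483647)
}

# radial boundary perturbation: Fourier series in polar angle, <= 5 harmonics,
# rescaled so its maximum magnitude equals `amplitude` pixels
sample_boundary_perturbation <- function(amplitude) {
  coef_cos <- stats::rnorm(5); coef_sin <- stats::rnorm(5)
  function(psi) {
    if (amplitude == 0) return(rep(0, length(psi)))
    g <- outer(psi, 1:5, function(p, k) cos(k * p)) %*% coef_cos +
      outer(psi, 1:5, function(p, k) sin(k * p)) %*% coef_sin
    gmax <- max(abs(range(outer(seq(0, 2 * pi, length.out = 720), 1:5,
                                function(p, k) cos(k * p)) %*% coef_cos +
                          outer(seq(0, 2 * pi, length.out = 720), 1:5,
                                function(p, k) sin(k * p)) %*% coef_sin)))
    as.numeric(g) / gmax * amplitude
  }
}

#' Generate one synthetic embryo image
#'
#' @param spec A [synthetic_spec()].
#' @param index Image index (1-based); with [generate_dataset()]'s default of
#'   one image per gene, image `index` shows gene `index`.
#' @param gene Gene shown in this image (defaults to `index`).
#' @return A list with `image` (H x W matrix, gray values in `[0, 255]`) and
#'   `truth` (a `synthetic_truth`: `mask`, ordered `boundary_pixels`,
#'   `gene_cluster_labels` for all genes, and the `domain_layout` needed to
#'   label mesh elements). Deterministic for fixed `(spec, index)`.
#' @export
generate_embryo <- function(spec, index, gene = index) {
  stopifnot(inherits(spec, "synthetic_spec"), index >= 1)
  if (gene > spec$n_genes) rlang::abort("gene index exceeds n_genes")
  H <- spec$image_size[1]; W <- spec$image_size[2]
  e <- spec$base_ellipse
  rng_state <- set_local_seed(image_seed(spec$seed, index))
  on.exit(restore_seed(rng_state), add = TRUE)
  delta <- sample_boundary_perturbation(spec$boundary_noise_amplitude)
  # pixel centers in the ellipse frame
  xs <- rep(seq_len(W) - 0.5, each = H)
  ys <- rep(seq_len(H) - 0.5, times = W)
  ct <- cos(e$theta); st <- sin(e$theta)
  xf <- (xs - e$cx) * ct + (ys - e$cy) * st
  yf <- -(xs - e$cx) * st + (ys - e$cy) * ct
  rp <- sqrt(xf^2 + yf^2)
  psi <- atan2(yf, xf)
  # base ellipse radius along each ray, perturbed radially in pixels
  re <- e$a * e$b / sqrt((e$b * cos(psi))^2 + (e$a * sin(psi))^2)
  rb <- re + delta(psi)
  if (any(rb <= 0)) rlang::abort("boundary perturbation too large: boundary self-intersects")
  inside <- rp <= rb
  mask <- matrix(inside, nrow = H)
  img <- matrix(0, H, W)
  img[mask] <- spec$background_level
  # paint this gene's domains in the ellipse-normalized frame
  u <- xf / e$a; v <- yf / e$b
  lay <- spec$domain_layout
  for (r in seq_len(nrow(lay))) {
    if (!(gene %in% lay$genes[[r]])) next
    dom <- inside & u >= lay$u_min[r] & u <= lay$u_max[r] &
      v >= lay$v_min[r] & v <= lay$v_max[r]
    img[matrix(dom, nrow = H)] <- lay$level[r]
  }
  if (spec$pixel_noise_sd > 0) {
    noise <- matrix(stats::rnorm(H * W, 0, spec$pixel_noise_sd), H, W)
    img[mask] <- img[mask] + noise[mask]
  }
  img <- pmin(pmax(img, 0), 255)
  truth <- structure(list(mask = mask,
                          boundary_pixels = extract_boundary(mask, image_id = index),
                          gene_cluster_labels = gene_truth_labels(spec),
                          domain_layout = lay),
                     class = "synthetic_truth")
  list(image = img, truth = truth)
}

# per-gene planted cluster label: the (first) domain a gene belongs to,
# 0 for flat-background genes
gene_truth_labels <- function(spec) {
  lab <- integer(spec$n_genes)
  lay <- spec$domain_layout
  for (r in seq_len(nrow(lay))) {
    g <- lay$genes[[r]]
    lab[g[lab[g] == 0L]] <- lay$domain[r]
  }
  lab
}

#' Generate a full synthetic dataset
#'
#' One image per gene by default; genes listed in `images_per_gene` with a
#' count above one get several images, which appear as separate rows of the
#' gene-image table (multiple images of one gene are treated separately
#' throughout the pipeline).
#'
#' @param spec A [synthetic_spec()].
#' @param images_per_gene Integer vector of length `n_genes` (default all 1).
#' @param dir Optional directory: when given, images are written as PNG, the
#'   gene-image table as TSV (`gene_id`, `image_path`) and the ground truth as
#'   JSON, and `image_path` points at the files.
#' @return A list with `images` (list of H x W matrices), `table` (tibble:
#'   `gene_id`, `image_id`, `image_path`), and `truths` (one
#'   `synthetic_truth` per image).
#' @export
generate_dataset <- function(spec, images_per_gene = NULL, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(images_per_gene)) images_per_gene <- rep(1L, spec$n_genes)
  stopifnot(length(images_per_gene) == spec$n_genes, all(images_per_gene >= 1))
  genes <- rep(seq_len(spec$n_genes), times = images_per_gene)
  n_img <- length(genes)
  out <- purrr::map(seq_len(n_img), function(i) generate_embryo(spec, i, gene = genes[i]))
  images <- purrr::map(out, "image")
  truths <- purrr::map(out, "truth")
  tab <- tibble::tibble(gene_id = sprintf("gene%03d", genes),
                        image_id = sprintf("img%03d", seq_len(n_img)),
                        image_path = NA_character_)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    tab$image_path <- file.path(dir, paste0(tab$image_id, ".png"))
    purrr::walk2(images, tab$image_path, write_gray_png)
    readr::write_tsv(tab[, c("gene_id", "image_path")], file.path(dir, "gene_image_table.tsv"))
    truth_json <- list(
      gene_cluster_labels = truths[[1]]$gene_cluster_labels,
      domain_layout = as.data.frame(dplyr::mutate(
        spec$domain_layout, genes = purrr::map_chr(genes, paste, collapse = ","))),
      seed = spec$seed)
    jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(images = images, table = tab, truths = truths)
}

# label mesh elements by the planted domain containing their centroid
# (in the base ellipse's normalized frame); 0 = outside every domain
label_mesh_elements <- function(mesh, base_ellipse, domain_layout) {
  td <- tidy.tri_mesh(mesh)
  uv <- ellipse_normalize(base_ellipse, td$cx, td$cy)
  lab <- integer(nrow(td))
  for (r in seq_len(nrow(domain_layout))) {
    hit <- uv[, 1] >= domain_layout$u_min[r] & uv[, 1] <= domain_layout$u_max[r] &
      uv[, 2] >= domain_layout$v_min[r] & uv[, 2] <= domain_layout$v_max[r]
    lab[hit & lab == 0L] <- domain_layout$domain[r]
  }
  lab
}

# run code under a temporary RNG state, restoring the caller's stream
set_local_seed <- function(seed) {
  state <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  state
}

restore_seed <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
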