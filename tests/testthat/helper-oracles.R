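# Independent oracles and shared fixtures for the test suite.
# Oracles are deliberately naive (double loops, exhaustive sums) and share no
# code with the package implementations they check.

# ---- geometry oracles -------------------------------------------------------

# rasterize an ellipse mask directly from the implicit equation
raster_ellipse_mask <- function(e, H, W) {
  xs <- rep(seq_len(W) - 0.5, each = H)
  ys <- rep(seq_len(H) - 0.5, times = W)
  ct <- cos(e$theta); st <- sin(e$theta)
  u <- ((xs - e$cx) * ct + (ys - e$cy) * st) / e$a
  v <- (-(xs - e$cx) * st + (ys - e$cy) * ct) / e$b
  matrix(u^2 + v^2 <= 1, nrow = H)
}

disc_mask <- function(r, pad = 5) {
  n <- 2 * (r + pad)
  cx <- r + pad
  xs <- rep(seq_len(n) - 0.5, each = n)
  ys <- rep(seq_len(n) - 0.5, times = n)
  matrix((xs - cx)^2 + (ys - cx)^2 <= r^2, nrow = n)
}

# geometric ellipse fit oracle: minimize summed squared Sampson distances
# (first-order approximation of orthogonal distance) over the 5 parameters
sampson_fit_oracle <- function(x, y, init) {
  obj <- function(p) {
    cx <- p[1]; cy <- p[2]; a <- exp(p[3]); b <- exp(p[4]); th <- p[5]
    ct <- cos(th); st <- sin(th)
    u <- ((x - cx) * ct + (y - cy) * st) / a
    v <- (-(x - cx) * st + (y - cy) * ct) / b
    f <- u^2 + v^2 - 1
    # gradient of f wrt (x, y)
    gx <- 2 * u / a * ct - 2 * v / b * st
    gy <- 2 * u / a * st + 2 * v / b * ct
    sum(f^2 / (gx^2 + gy^2))
  }
  p0 <- c(init$cx, init$cy, log(init$a), log(init$b), init$theta)
  fit <- stats::optim(p0, obj, method = "BFGS", control = list(maxit = 500))
  list(cx = fit$par[1], cy = fit$par[2], a = exp(fit$par[3]),
       b = exp(fit$par[4]), theta = fit$par[5])
}

# exhaustive nearest-boundary-pixel search with lexicographic (row, col)
# tie-break, via a plain double loop
bf_project <- function(points, mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  bp <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    nb_bg <- (r == 1 || !mask[r - 1, c]) || (r == nr || !mask[r + 1, c]) ||
      (c == 1 || !mask[r, c - 1]) || (c == nc || !mask[r, c + 1])
    if (nb_bg) bp[[length(bp) + 1L]] <- c(r, c)
  }
  bp <- do.call(rbind, bp)
  bp <- bp[order(bp[, 1], bp[, 2]), , drop = FALSE]
  out <- matrix(0, nrow(points), 2)
  for (i in seq_len(nrow(points))) {
    best <- Inf; bj <- NA
    for (j in seq_len(nrow(bp))) {
      d <- (points[i, 1] - (bp[j, 2] - 0.5))^2 + (points[i, 2] - (bp[j, 1] - 0.5))^2
      if (d < best) { best <- d; bj <- j }
    }
    out[i, ] <- c(bp[bj, 2] - 0.5, bp[bj, 1] - 0.5)
  }
  out
}

# brute-force pixel-to-triangle assignment and per-element medians:
# pixel center belongs to the lowest-index triangle containing it
bf_element_medians <- function(image, vertices, triangles) {
  H <- nrow(image); W <- ncol(image)
  nt <- nrow(triangles)
  vals <- vector("list", nt)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    px <- c - 0.5; py <- r - 0.5
    for (t in seq_len(nt)) {
      p <- vertices[triangles[t, ], , drop = FALSE]
      d <- (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
        (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])
      l1 <- ((p[2, 2] - p[3, 2]) * (px - p[3, 1]) + (p[3, 1] - p[2, 1]) * (py - p[3, 2])) / d
      l2 <- ((p[3, 2] - p[1, 2]) * (px - p[3, 1]) + (p[1, 1] - p[3, 1]) * (py - p[3, 2])) / d
      l3 <- 1 - l1 - l2
      if (l1 >= -1e-9 && l2 >= -1e-9 && l3 >= -1e-9) {
        vals[[t]] <- c(vals[[t]], image[r, c])
        break
      }
    }
  }
  vapply(seq_len(nt), function(t) {
    if (is.null(vals[[t]])) 0 else stats::median(vals[[t]])
  }, numeric(1))
}

# ---- co-clustering oracles --------------------------------------------------

naive_loglik <- function(A, P, Q) {
  s <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    if (A[i, j] > 0) s <- s + A[i, j] * log(sum(P[i, ] * Q[j, ]))
  }
  2 * s
}

# explicit-responsibility EM step: materialize phi_ijk and maximize the
# expected log likelihood directly under the column-sum constraints
explicit_em_oracle <- function(A, P, Q) {
  m <- nrow(A); n <- ncol(A); cc <- ncol(P)
  phi <- array(0, c(m, n, cc))
  for (i in seq_len(m)) for (j in seq_len(n)) {
    denom <- sum(P[i, ] * Q[j, ])
    for (k in seq_len(cc)) phi[i, j, k] <- P[i, k] * Q[j, k] / denom
  }
  Pn <- matrix(0, m, cc); Qn <- matrix(0, n, cc)
  for (k in seq_len(cc)) {
    for (i in seq_len(m)) Pn[i, k] <- sum(phi[i, , k] * A[i, ])
    for (j in seq_len(n)) Qn[j, k] <- sum(phi[, j, k] * A[, j])
    Pn[, k] <- Pn[, k] / sum(Pn[, k])
    Qn[, k] <- Qn[, k] / sum(Qn[, k])
  }
  list(P = Pn, Q = Qn)
}

random_pq <- function(m, n, cc) {
  P <- matrix(stats::runif(m * cc) + 0.05, m, cc)
  Q <- matrix(stats::runif(n * cc) + 0.05, n, cc)
  list(P = sweep(P, 2, colSums(P), "/"), Q = sweep(Q, 2, colSums(Q), "/"))
}

# exhaustive hypergeometric upper-tail probability via binomial coefficients
bf_hyper_tail <- function(k, s, K, N) {
  kk <- k:min(s, K)
  sum(choose(K, kk) * choose(N - K, s - kk)) / choose(N, s)
}

# ---- shared fixtures (built once per test run) ------------------------------

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small, fast generic mesh on a clean ellipse
small_mesh <- function() fixture("small_mesh", function() {
  mesh_ellipse(ellipse(100, 60, 80, 40), area_bound = 250)
})

# a 9-gene planted dataset (3 gene groups x 3 domains, high signal-to-noise)
# plus the full pipeline run on it at c = 3
planted_spec <- function() fixture("planted_spec", function() {
  synthetic_spec(n_genes = 9, seed = 421)
})

planted_run <- function() fixture("planted_run", function() {
  spec <- planted_spec()
  ds <- generate_dataset(spec)
  ann <- tibble::tibble(
    gene_id = sprintf("gene%03d", seq_len(spec$n_genes)),
    term_id = paste0("TERM:", gene_truth_labels_of(spec)))
  cfg <- pipeline_config(
    out_dir = file.path(tempdir(), "planted_run_out"),
    n_clusters = 3, images = ds$images, table = ds$table,
    masks = lapply(ds$truths, function(t) t$mask),
    annotations = ann, target_elements = 120, seed = 7)
  list(spec = spec, ds = ds, ann = ann, cfg = cfg,
       res = suppressWarnings(run_pipeline(cfg)))
})

gene_truth_labels_of <- function(spec) {
  lab <- integer(spec$n_genes)
  lay <- spec$domain_layout
  for (r in seq_len(nrow(lay))) {
    g <- lay$genes[[r]]
    lab[g[lab[g] == 0L]] <- lay$domain[r]
  }
  lab
}

# the 20-embryo set used by the mesh-requirements checks
embryo_set_20 <- function() fixture("embryo_set_20", function() {
  spec <- synthetic_spec(n_genes = 20, seed = 99)
  ds <- generate_dataset(spec)
  masks <- lapply(ds$truths, function(t) t$mask)
  fits <- fit_embryo_ellipses(masks, ids = ds$table$image_id)
  list(spec = spec, ds = ds, masks = masks, fits = fits)
})
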