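#' Create an ellipse
#'
#' An ellipse is described by its center (pixels), semi-axes (pixels) and the
#' rotation of its semi-major axis measured from the +x (anterior-posterior)
#' image axis. Rotation is stored in `[-pi/2, pi/2)`; ellipse orientation is
#' pi-periodic so this interval is a canonical representative.
#'
#' @param cx,cy Center, in pixel coordinates.
#' @param a Semi-major axis length (pixels); must satisfy `a >= b > 0`.
#' @param b Semi-minor axis length (pixels).
#' @param theta Rotation of the semi-major axis, radians.
#' @return An object of class `ellipse`.
#' @examples
#' ellipse(160, 80, 140, 60)
#' @export
ellipse <- function(cx, cy, a, b, theta = 0) {
  stopifnot(is.numeric(cx), is.numeric(cy), is.numeric(a), is.numeric(b),
            is.numeric(theta), length(cx) == 1L, length(theta) == 1L)
  if (!(a >= b && b > 0)) {
    rlang::abort("ellipse semi-axes must satisfy a >= b > 0")
  }
  theta <- wrap_half_pi(theta)
  structure(list(cx = cx, cy = cy, a = a, b = b, theta = theta),
            class = "ellipse")
}

# canonical representative of a pi-periodic orientation in [-pi/2, pi/2)
wrap_half_pi <- function(theta) {
  t <- (theta + pi / 2) %% pi - pi / 2
  if (t >= pi / 2) t <- t - pi
  t
}

#' @export
print.ellipse <- function(x, ...) {
  cat(sprintf("<ellipse> center (%.2f, %.2f), semi-axes (%.2f, %.2f), rotation %.4f rad\n",
              x$cx, x$cy, x$a, x$b, x$theta))
  invisible(x)
}

#' @export
format.ellipse <- function(x, ...) {
  sprintf("ellipse(cx=%g, cy=%g, a=%g, b=%g, theta=%g)", x$cx, x$cy, x$a, x$b, x$theta)
}

#' Point on an ellipse at a parametric angle
#'
#' Evaluates the ellipse at parametric angle `angle` (radians, measured in the
#' ellipse's own frame) and maps the point to image coordinates. At angle 0 the
#' point is the semi-major vertex; at `pi/2` the semi-minor vertex.
#'
#' @param ellipse An [ellipse()].
#' @param angle Parametric angle(s), radians. Vectorized.
#' @return A two-column matrix of (x, y) image coordinates, one row per angle.
#' @examples
#' arc_point(ellipse(0, 0, 4, 2), c(0, pi / 2))
#' @export
arc_point <- function(ellipse, angle) {
  stopifnot(inherits(ellipse, "ellipse"), is.numeric(angle), all(is.finite(angle)))
  ct <- cos(ellipse$theta); st <- sin(ellipse$theta)
  px <- ellipse$a * cos(angle); py <- ellipse$b * sin(angle)
  cbind(x = ellipse$cx + px * ct - py * st,
        y = ellipse$cy + px * st + py * ct)
}

# map image coordinates into the ellipse-normalized frame:
# u along the major axis / a, v along the minor axis / b; the unit circle
# u^2 + v^2 = 1 is the ellipse itself.
ellipse_normalize <- function(ellipse, x, y) {
  ct <- cos(ellipse$theta); st <- sin(ellipse$theta)
  dx <- x - ellipse$cx; dy <- y - ellipse$cy
  cbind(u = (dx * ct + dy * st) / ellipse$a,
        v = (-dx * st + dy * ct) / ellipse$b)
}

ellipse_area <- function(ellipse) pi * ellipse$a * ellipse$b

# perimeter and arc-length table via a dense polyline in parametric angle;
# the same table drives the subdivision so chord placement is self-consistent
ellipse_arclength_table <- function(ellipse, n = 8192L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  p <- arc_point(ellipse, th)
  nxt <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  seg <- sqrt(rowSums((nxt - p)^2))
  list(theta = th, points = p, seg = seg, cum = c(0, cumsum(seg)),
       perimeter = sum(seg))
}

ellipse_perimeter <- function(ellipse) ellipse_arclength_table(ellipse)$perimeter

#' Extract the ordered outer boundary of a mask
#'
#' Traces the outer boundary of a binary mask (Moore-neighbor tracing) and
#' returns the boundary pixel centers in order. A pixel center at matrix
#' position (row r, column c) has coordinates `x = c - 0.5`, `y = r - 0.5`.
#' The loop is oriented so that its shoelace signed area in these coordinates
#' is positive, matching the direction of increasing parametric angle used
#' elsewhere in the package.
#'
#' @param mask A logical or 0/1 matrix with exactly one 4-connected
#'   foreground component.
#' @param image_id Optional identifier attached to the result.
#' @return A tibble with columns `x`, `y` (ordered boundary pixel centers) of
#'   class `boundary_pixels`; the source id is kept in attribute `image_id`.
#' @export
extract_boundary <- function(mask, image_id = NULL) {
  mask <- as_mask(mask)
  if (!any(mask)) rlang::abort("mask is empty: no foreground pixels")
  if (n_components(mask) != 1L) {
    rlang::abort("mask must contain exactly one 4-connected foreground component")
  }
  rc <- trace_moore(mask)
  out <- tibble::tibble(x = rc[, 2] - 0.5, y = rc[, 1] - 0.5)
  # orient to positive shoelace area
  if (polygon_signed_area(out$x, out$y) < 0) out <- out[rev(seq_len(nrow(out))), ]
  attr(out, "image_id") <- image_id
  class(out) <- c("boundary_pixels", class(out))
  out
}

as_mask <- function(mask) {
  if (!is.matrix(mask)) rlang::abort("mask must be a matrix")
  mask > 0
}

polygon_signed_area <- function(x, y) {
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

# number of 4-connected foreground components: union-find over the vertical
# runs of each column (exact and fast; no iterative dilation)
n_components <- function(mask) {
  nr <- nrow(mask)
  v <- as.vector(rbind(mask, FALSE))  # sentinel row stops runs at column ends
  starts <- which(diff(c(FALSE, v)) == 1L)
  if (!length(starts)) return(0L)
  ends <- which(diff(c(v, FALSE)) == -1L)
  col <- (starts - 1L) %/% (nr + 1L) + 1L
  r0 <- (starts - 1L) %% (nr + 1L) + 1L
  r1 <- (ends - 1L) %% (nr + 1L) + 1L
  nrun <- length(starts)
  parent <- seq_len(nrun)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  runs_by_col <- split(seq_len(nrun), col)
  cols <- as.integer(names(runs_by_col))
  for (ci in seq_along(cols)[-1]) {
    if (cols[ci] != cols[ci - 1L] + 1L) next
    for (i in runs_by_col[[ci]]) {
      for (j in runs_by_col[[ci - 1L]]) {
        if (r0[i] <= r1[j] && r1[i] >= r0[j]) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  length(unique(vapply(seq_len(nrun), find, integer(1L))))
}

# Moore-neighbor boundary tracing with Jacob's stopping criterion.
# Returns (row, col) pixels of the outer contour in trace order.
trace_moore <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  nrp <- nr + 2L
  pad <- matrix(FALSE, nrp, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  # clockwise Moore neighborhood starting west: (dr, dc)
  offr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  offc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  offlin <- offr + offc * nrp
  # enter_next[d]: search start when the trace moved in direction d; this is
  # the neighbor just after the backtrack (off[d-1] relative to the new pixel)
  enter_next <- integer(8L)
  for (d in 1:8) {
    prev <- ((d - 2L) %% 8L) + 1L
    back_r <- offr[prev] - offr[d]; back_c <- offc[prev] - offc[d]
    enter_next[d] <- which(offr == back_r & offc == back_c)
  }
  padv <- as.vector(pad)
  # raster-order (row-major) start pixel: lowest row, then lowest column
  idx <- which(pad, arr.ind = TRUE)
  o <- order(idx[, 1], idx[, 2])
  start_r <- idx[o[1], 1]; start_c <- idx[o[1], 2]
  start <- start_r + (start_c - 1L) * nrp
  if (length(which(padv)) == 1L) {
    return(matrix(c(start_r - 1L, start_c - 1L), ncol = 2L))
  }
  maxlen <- sum(padv) * 4L + 8L
  path <- integer(maxlen)
  np <- 1L
  path[1L] <- start
  cur <- start
  enter <- 1L
  first_dir <- NA_integer_
  repeat {
    found <- FALSE
    for (k in 0:7) {
      d <- ((enter - 1L + k) %% 8L) + 1L
      cand <- cur + offlin[d]
      if (padv[cand]) {
        # Jacob: stop when re-entering the start pixel in the initial direction
        if (cand == start && !is.na(first_dir) && d == first_dir) {
          return(lin_to_rc(path[seq_len(np)], nrp))
        }
        if (is.na(first_dir)) first_dir <- d
        np <- np + 1L
        path[np] <- cand
        enter <- enter_next[d]
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found || np >= maxlen) {
      return(unique_rows(lin_to_rc(path[seq_len(np)], nrp)))
    }
  }
}

lin_to_rc <- function(lin, nrp) {
  r <- (lin - 1L) %% nrp + 1L
  c <- (lin - 1L) %/% nrp + 1L
  cbind(r - 1L, c - 1L)
}

unique_rows <- function(m) m[!duplicated(m), , drop = FALSE]

#' Fit an ellipse to boundary pixels by least squares
#'
#' Direct (algebraic) least-squares conic fit with the ellipse-specific
#' constraint \eqn{4AC - B^2 = 1} (the numerically stable formulation of
#' Halir & Flusser), followed by conversion to geometric center/axes/rotation
#' parameters. The fit is closed-form and deterministic. Points are centered
#' and isotropically scaled for conditioning before fitting.
#'
#' @param boundary A [extract_boundary()] result, or any data frame / matrix
#'   with columns `x`, `y` (at least 5 non-collinear points).
#' @return An [ellipse()].
#' @examples
#' th <- seq(0, 2 * pi, length.out = 100)
#' pts <- data.frame(x = 50 + 40 * cos(th), y = 40 + 20 * sin(th))
#' fit_ellipse(pts)
#' @export
fit_ellipse <- function(boundary) {
  xy <- as_xy(boundary)
  x <- xy[, 1]; y <- xy[, 2]
  if (length(x) < 5L) rlang::abort("ellipse fitting needs at least 5 points")
  mx <- mean(x); my <- mean(y)
  s <- mean(c(stats::sd(x), stats::sd(y)))
  if (!is.finite(s) || s <= 0) rlang::abort("degenerate point set: no spread")
  u <- (x - mx) / s; v <- (y - my) / s
  D1 <- cbind(u^2, u * v, v^2)
  D2 <- cbind(u, v, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  if (rcond_sym(S3) < 1e-12) rlang::abort("degenerate point set (collinear?)")
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  ok <- which(cond > 0)
  if (!length(ok)) rlang::abort("point set does not determine an ellipse")
  a1 <- vecs[, ok[1]]
  conic <- c(a1, as.vector(Tm %*% a1))  # (A, B, C, D, E, F) in normalized frame
  geo <- conic_to_geometric(conic)
  ellipse(cx = mx + s * geo$cx, cy = my + s * geo$cy,
          a = s * geo$a, b = s * geo$b, theta = geo$theta)
}

as_xy <- function(boundary) {
  if (is.matrix(boundary)) {
    stopifnot(ncol(boundary) >= 2)
    return(boundary[, 1:2, drop = FALSE])
  }
  stopifnot(all(c("x", "y") %in% names(boundary)))
  cbind(boundary$x, boundary$y)
}

rcond_sym <- function(m) {
  e <- abs(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  min(e) / max(e)
}

# conic (A,B,C,D,E,F) with 4AC - B^2 > 0 -> center/axes/rotation
conic_to_geometric <- function(k) {
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; F <- k[6]
  ctr <- solve(matrix(c(2 * A, B, B, 2 * C), 2), -c(D, E))
  F0 <- A * ctr[1]^2 + B * ctr[1] * ctr[2] + C * ctr[2]^2 + D * ctr[1] + E * ctr[2] + F
  M2 <- matrix(c(A, B / 2, B / 2, C), 2)
  ev <- eigen(M2, symmetric = TRUE)
  ax <- sqrt(-F0 / ev$values)  # one per eigenvalue
  if (any(!is.finite(ax))) rlang::abort("conic is not a real ellipse")
  ord <- order(ax, decreasing = TRUE)
  major_vec <- ev$vectors[, ord[1]]
  list(cx = ctr[1], cy = ctr[2], a = ax[ord[1]], b = ax[ord[2]],
       theta = wrap_half_pi(atan2(major_vec[2], major_vec[1])))
}

# algebraic conic residual of points on an ellipse (0 when exactly on it),
# normalized so it is invariant to conic scaling
conic_residual <- function(ellipse, xy) {
  uv <- ellipse_normalize(ellipse, xy[, 1], xy[, 2])
  uv[, 1]^2 + uv[, 2]^2 - 1
}

#' Average a list of ellipses into a generic ellipse
#'
#' Center and semi-axes are averaged arithmetically; rotation is averaged with
#' a circular mean on twice the angle, which respects the pi-periodicity of
#' ellipse orientation (so +0.1 and -0.1 rad average to 0, not to a meaningless
#' branch-dependent value).
#'
#' @param ellipses A non-empty list of [ellipse()] objects.
#' @return The average [ellipse()].
#' @export
average_ellipses <- function(ellipses) {
  if (!length(ellipses)) rlang::abort("cannot average an empty list of ellipses")
  stopifnot(all(vapply(ellipses, inherits, logical(1), "ellipse")))
  g <- function(f) vapply(ellipses, `[[`, numeric(1), f)
  two_theta <- 2 * g("theta")
  theta <- atan2(mean(sin(two_theta)), mean(cos(two_theta))) / 2
  ellipse(cx = mean(g("cx")), cy = mean(g("cy")),
          a = mean(g("a")), b = mean(g("b")), theta = wrap_half_pi(theta))
}

#' Fit ellipses to a set of masks and average them
#'
#' Convenience wrapper: extracts each mask's boundary, fits an ellipse to it,
#' and returns the per-image fits together with their average (the generic
#' ellipse on which the shared mesh is built).
#'
#' @param masks A list of binary masks.
#' @param ids Optional image identifiers (defaults to list names or indices).
#' @return A list with `fits` (tibble: image_id, cx, cy, a, b, theta),
#'   `ellipses` (list of [ellipse()]) and `average` (an [ellipse()]).
#' @export
fit_embryo_ellipses <- function(masks, ids = NULL) {
  if (is.null(ids)) ids <- names(masks) %||% as.character(seq_along(masks))
  ells <- purrr::map2(masks, ids, function(m, id) fit_ellipse(extract_boundary(m, id)))
  fits <- purrr::map2_dfr(ells, ids, function(e, id) {
    tibble::tibble(image_id = id, cx = e$cx, cy = e$cy, a = e$a, b = e$b, theta = e$theta)
  })
  list(fits = fits, ellipses = ells, average = average_ellipses(ells))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
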