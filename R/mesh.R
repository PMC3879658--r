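#' Side length of an equilateral triangle with a given area
#'
#' The boundary of the generic ellipse is subdivided into segments of roughly
#' this length so that boundary triangles of the target area `a` come out close
#' to equilateral: \eqn{\ell = \sqrt{4a/\sqrt{3}}}.
#'
#' @param area_bound Target triangle area `a` (square pixels), > 0.
#' @return The equilateral side length (pixels).
#' @examples
#' equilateral_side(sqrt(3) / 4)  # 1
#' @export
equilateral_side <- function(area_bound) {
  stopifnot(is.numeric(area_bound))
  if (any(area_bound <= 0)) rlang::abort("area bound must be positive")
  sqrt(4 * area_bound / sqrt(3))
}

#' Subdivide an ellipse boundary into equal-length chords
#'
#' Places `s = ceiling(perimeter / edge_length)` vertices on the ellipse so
#' that all consecutive chord lengths are equal (to well below `tolerance`),
#' by stepping a fixed chord around a dense polyline of the boundary and
#' solving for the chord length that closes the loop after exactly `s` steps.
#' The subdivision is uniform with respect to segment length, not radial
#' angle: on an elongated ellipse the angular gaps vary while the chords do
#' not.
#'
#' @param ellipse An [ellipse()].
#' @param edge_length Target segment length \eqn{\ell} (pixels); must allow at
#'   least 3 vertices on the boundary.
#' @param tolerance Maximum admissible relative spread among chord lengths.
#' @return A `boundary_subdivision`: list with `angles` (strictly increasing
#'   parametric angles in `[0, 2pi)`), `vertices` (s x 2 matrix), `edge_length`
#'   (the requested \eqn{\ell}), `chord` (the realized common chord length) and
#'   `tolerance`.
#' @export
subdivide_boundary <- function(ellipse, edge_length, tolerance = 0.01) {
  stopifnot(inherits(ellipse, "ellipse"), edge_length > 0)
  tab <- ellipse_arclength_table(ellipse)
  per <- tab$perimeter
  if (edge_length >= per / 3) {
    rlang::abort("edge length too large: fewer than 3 boundary vertices would fit")
  }
  s <- max(3L, as.integer(ceiling(per / edge_length)))
  walk <- function(d) chord_walk(tab, d, s)
  # bisect on the common chord so that s chords close the loop exactly
  lo <- 0.5 * per / s; hi <- min(1.5 * per / s, 0.999 * per / 3)
  f <- function(d) walk(d)$arc_total - per
  flo <- f(lo); fhi <- f(hi)
  if (flo > 0 || fhi < 0) rlang::abort("boundary subdivision failed to bracket the chord length")
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  d <- (lo + hi) / 2
  w <- walk(d)
  v <- w$vertices; ang <- w$theta
  chords <- sqrt(rowSums((rbind(v[-1, ], v[1, ]) - v)^2))
  spread <- (max(chords) - min(chords)) / mean(chords)
  if (spread > tolerance) {
    rlang::abort(sprintf("chord spread %.3g exceeds tolerance %.3g", spread, tolerance))
  }
  structure(list(angles = ang, vertices = v, edge_length = edge_length,
                 chord = mean(chords), tolerance = tolerance),
            class = "boundary_subdivision")
}

# step a chord of length d around the dense boundary polyline s times,
# starting from parametric angle 0; returns vertices, their parametric angles,
# and the total arc length traversed (used to close the loop)
chord_walk <- function(tab, d, s) {
  P <- tab$points
  n <- nrow(P)
  dth <- 2 * pi / n
  cum <- tab$cum  # arc length at each dense sample, length n+1
  per <- cum[n + 1L]
  verts <- matrix(0, s, 2)
  theta <- numeric(s)
  q <- P[1, ]; verts[1, ] <- q; theta[1] <- 0
  j <- 1L          # last dense index at or before current point (1-based)
  arc_q <- 0       # arc position of current point
  d2 <- d^2
  dist2 <- function(jabs) {
    p <- P[(jabs - 1L) %% n + 1L, ]
    (p[1] - q[1])^2 + (p[2] - q[2])^2
  }
  for (k in 2:(s + 1L)) {
    # jump close to the crossing via the arc-length table (chord <= arc),
    # then adjust by single steps
    target <- arc_q + 0.98 * d
    wrap <- (target %/% per)
    jg <- findInterval(target - wrap * per, cum) + as.integer(wrap) * n
    if (jg > j) j <- jg
    while (j > 1L && dist2(j) >= d2) j <- j - 1L
    repeat {
      if (dist2(j + 1L) >= d2) break
      j <- j + 1L
      if (j > 3L * n) rlang::abort("chord walk failed to advance")
    }
    # exact crossing on segment [P[j], P[j+1]] (indices wrapped)
    i0 <- (j - 1L) %% n + 1L; i1 <- j %% n + 1L
    a <- P[i0, ]; b <- P[i1, ]
    t <- chord_cross(a, b, q, d)
    pt <- a + t * (b - a)
    seglen <- sqrt(sum((b - a)^2))
    arc_here <- wrap_cum(cum, j - 1L, n) + t * seglen
    th_here <- ((i0 - 1L) + t) * dth
    if (k <= s) { verts[k, ] <- pt; theta[k] <- th_here }
    q <- pt
    arc_q <- arc_here
    if (k == s + 1L) return(list(vertices = verts, theta = theta, arc_total = arc_here))
  }
}

wrap_cum <- function(cum, j0, n) {
  # arc length at dense sample index j0 (0-based, may exceed n for wrapped walks)
  full <- j0 %/% n
  rem <- j0 %% n
  full * cum[n + 1L] + cum[rem + 1L]
}

# smallest t in [0,1] with |a + t(b-a) - q| = d (largest root of the quadratic;
# the walk guarantees |a-q| < d <= |b-q|)
chord_cross <- function(a, b, q, d) {
  u <- b - a; w <- a - q
  A <- sum(u^2); B <- 2 * sum(u * w); C <- sum(w^2) - d^2
  disc <- max(B^2 - 4 * A * C, 0)
  t <- (-B + sqrt(disc)) / (2 * A)
  min(max(t, 0), 1)
}

#' Assemble the planar straight-line graph for meshing
#'
#' The PSLG consists of the boundary subdivision vertices joined by
#' consecutive segments into a single closed loop, plus one isolated point at
#' the ellipse center. The mesher preserves all of these: boundary segments
#' are never split.
#'
#' @param subdivision A [subdivide_boundary()] result.
#' @param ellipse The [ellipse()] the subdivision was built on.
#' @return A `pslg`: list with `points` ((s+1) x 2; rows 1..s are the boundary
#'   loop, row s+1 the center) and `segments` (s x 2 vertex index pairs).
#' @export
build_pslg <- function(subdivision, ellipse) {
  stopifnot(inherits(subdivision, "boundary_subdivision"), inherits(ellipse, "ellipse"))
  s <- nrow(subdivision$vertices)
  structure(list(points = rbind(subdivision$vertices, c(ellipse$cx, ellipse$cy)),
                 segments = cbind(seq_len(s), c(seq_len(s)[-1], 1L)),
                 n_boundary = s),
            class = "pslg")
}

#' Quality triangulation of a PSLG with area and angle bounds
#'
#' Produces a conforming Delaunay triangulation of the region bounded by the
#' PSLG loop in which every PSLG segment appears unsplit as a mesh edge, every
#' triangle has area at most `area_bound`, and every interior angle is at
#' least `angle_bound` degrees. The refiner seeds the interior with a
#' hexagonal vertex lattice matched to the target element size, smooths vertex
#' positions (boundary and center fixed), and then inserts Steiner points
#' (circumcenters, falling back to centroids near the boundary) until both
#' bounds hold. Fully deterministic.
#'
#' @param pslg A [build_pslg()] result.
#' @param area_bound Maximum triangle area `a` (square pixels).
#' @param angle_bound Minimum interior angle in degrees; at most 25 (larger
#'   bounds are not guaranteed to terminate).
#' @return A `tri_mesh`: list with `vertices` (V x 2), `triangles` (T x 3
#'   integer, counter-clockwise, in a fixed canonical order),
#'   `boundary_vertex_ids` (= 1..s, matching the subdivision order),
#'   `area_bound`, `angle_bound`.
#' @export
triangulate <- function(pslg, area_bound, angle_bound = 25) {
  stopifnot(inherits(pslg, "pslg"), area_bound > 0)
  if (angle_bound > 25) {
    rlang::abort("angle bounds above 25 degrees may not terminate; use <= 25")
  }
  s <- pslg$n_boundary
  bd <- pslg$points[seq_len(s), , drop = FALSE]
  fixed <- pslg$points
  nfix <- nrow(fixed)
  ell <- equilateral_side(area_bound)
  pts <- rbind(fixed, seed_lattice(bd, fixed, 0.88 * ell))
  tri <- delaunay(pts)
  for (it in 1:15) {
    pts <- smooth_interior(pts, tri, nfix)
    if (it %% 3 == 0 || it == 15) tri <- delaunay(pts)
  }
  # refinement: insert spaced Steiner points for violating triangles, smooth,
  # repeat. Candidates closer than 0.45 * ell to any existing or accepted
  # point are rejected, so the vertex set satisfies a packing bound and the
  # loop terminates; smoothing repairs the angles such blocked insertions
  # would have addressed.
  stalled <- 0L
  for (pass in 1:60) {
    q <- triangle_quality(pts, tri)
    bad <- which(q$area > area_bound | q$min_angle < angle_bound)
    if (!length(bad)) break
    cand <- steiner_points(pts, tri, bad, bd)
    cand <- filter_spaced(cand, pts, 0.45 * ell)
    stalled <- if (nrow(cand)) 0L else stalled + 1L
    if (stalled > 6L) break  # smoothing alone is not converging
    if (nrow(cand)) {
      pts <- rbind(pts, cand)
      tri <- delaunay(pts)
    }
    pts <- smooth_interior(smooth_interior(pts, tri, nfix), tri, nfix)
    tri <- delaunay(pts)
  }
  q <- triangle_quality(pts, tri)
  viol <- which(q$area > area_bound * (1 + 1e-12) | q$min_angle < angle_bound - 1e-9)
  if (length(viol)) {
    w <- viol[1]
    rlang::abort(sprintf(
      "refinement failed: triangle %d (vertices %s) has area %.4g, min angle %.3g deg",
      w, paste(tri[w, ], collapse = ","), q$area[w], q$min_angle[w]))
  }
  check_segments_present(tri, pslg$segments)
  ord <- order(tri[, 1], tri[, 2], tri[, 3])
  tri <- canonical_rotation(tri)[ord, , drop = FALSE]
  structure(list(vertices = pts, triangles = tri,
                 boundary_vertex_ids = seq_len(s),
                 area_bound = area_bound, angle_bound = angle_bound),
            class = "tri_mesh")
}

# rotate each (CCW) triple so the smallest vertex id comes first; preserves
# orientation and gives a canonical, stable element numbering after sorting
canonical_rotation <- function(tri) {
  k <- max.col(-tri, ties.method = "first")  # column of the minimum
  r1 <- tri; r2 <- tri[, c(2, 3, 1), drop = FALSE]; r3 <- tri[, c(3, 1, 2), drop = FALSE]
  out <- r1
  out[k == 2, ] <- r2[k == 2, , drop = FALSE]
  out[k == 3, ] <- r3[k == 3, , drop = FALSE]
  out
}

check_segments_present <- function(tri, segments) {
  ed <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  want <- paste(pmin(segments[, 1], segments[, 2]), pmax(segments[, 1], segments[, 2]))
  missing <- want[!(want %in% key)]
  if (length(missing)) {
    rlang::abort(sprintf("PSLG segment(s) not present in mesh: %s",
                         paste(missing, collapse = "; ")))
  }
  invisible(TRUE)
}

# hexagonal interior lattice with deterministic sub-pixel jitter (avoids the
# exactly-cocircular point quadruples of a perfect lattice); points are kept
# clear of the boundary polygon and of the fixed PSLG points
seed_lattice <- function(bd_polygon, fixed_pts, h) {
  xr <- range(bd_polygon[, 1]); yr <- range(bd_polygon[, 2])
  xs <- seq(xr[1], xr[2], by = h)
  ys <- seq(yr[1], yr[2], by = h * sqrt(3) / 2)
  lat <- do.call(rbind, lapply(seq_along(ys), function(i) {
    cbind(xs + if (i %% 2 == 0) h / 2 else 0, ys[i])
  }))
  idx <- seq_len(nrow(lat))
  lat[, 1] <- lat[, 1] + 0.02 * h * (((idx * 2654435761) %% 1024) / 1024 - 0.5)
  lat[, 2] <- lat[, 2] + 0.02 * h * (((idx * 40503) %% 1024) / 1024 - 0.5)
  keep <- point_in_polygon(lat, bd_polygon) &
    dist_to_polygon(lat, bd_polygon) > 0.7 * h
  lat <- lat[keep, , drop = FALSE]
  if (!nrow(lat)) return(lat)
  d2min <- apply(fixed_pts, 1, function(p) (lat[, 1] - p[1])^2 + (lat[, 2] - p[2])^2)
  d2min <- if (is.matrix(d2min)) apply(d2min, 1, min) else min(d2min)
  lat[d2min > (0.5 * h)^2, , drop = FALSE]
}

point_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  x <- pts[, 1]; y <- pts[, 2]
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

dist_to_polygon <- function(pts, poly) {
  n <- nrow(poly)
  d2 <- rep(Inf, nrow(pts))
  nxt <- c(2:n, 1L)
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[nxt[i], ]
    u <- b - a
    L2 <- sum(u^2)
    t <- pmin(pmax(((pts[, 1] - a[1]) * u[1] + (pts[, 2] - a[2]) * u[2]) / L2, 0), 1)
    dd <- (pts[, 1] - (a[1] + t * u[1]))^2 + (pts[, 2] - (a[2] + t * u[2]))^2
    d2 <- pmin(d2, dd)
  }
  sqrt(d2)
}

circumcircles <- function(P, tri) {
  a1 <- P[tri[, 1], 1]; a2 <- P[tri[, 1], 2]
  b1 <- P[tri[, 2], 1]; b2 <- P[tri[, 2], 2]
  c1 <- P[tri[, 3], 1]; c2 <- P[tri[, 3], 2]
  d <- 2 * (a1 * (b2 - c2) + b1 * (c2 - a2) + c1 * (a2 - b2))
  aa <- a1^2 + a2^2; bb <- b1^2 + b2^2; cc <- c1^2 + c2^2
  ux <- (aa * (b2 - c2) + bb * (c2 - a2) + cc * (a2 - b2)) / d
  uy <- (aa * (c1 - b1) + bb * (a1 - c1) + cc * (b1 - a1)) / d
  cbind(ux, uy, (ux - a1)^2 + (uy - a2)^2)
}

# incremental Bowyer-Watson Delaunay triangulation; deterministic insertion
# order (input order); triangles returned counter-clockwise
delaunay <- function(pts) {
  n <- nrow(pts)
  stopifnot(n >= 3)
  xr <- range(pts[, 1]); yr <- range(pts[, 2])
  dmax <- max(diff(xr), diff(yr)) * 20
  cx <- mean(xr); cy <- mean(yr)
  P <- rbind(c(cx - dmax, cy - dmax / 2), c(cx + dmax, cy - dmax / 2),
             c(cx, cy + dmax), pts)
  cap <- 2L * n + 64L
  T1 <- integer(cap); T2 <- integer(cap); T3 <- integer(cap)
  CX <- numeric(cap); CY <- numeric(cap); R2 <- numeric(cap)
  alive <- logical(cap)
  T1[1] <- 1L; T2[1] <- 2L; T3[1] <- 3L; alive[1] <- TRUE
  cc <- circumcircles(P, matrix(1:3, 1))
  CX[1] <- cc[1]; CY[1] <- cc[2]; R2[1] <- cc[3]
  ntri <- 1L
  free <- integer(0)
  nvirt <- n + 3L
  for (ip in seq_len(n)) {
    p1 <- pts[ip, 1]; p2 <- pts[ip, 2]; pid <- ip + 3L
    act <- which(alive[seq_len(ntri)])
    bad <- act[(p1 - CX[act])^2 + (p2 - CY[act])^2 <= R2[act] * (1 + 1e-12)]
    e1 <- c(T1[bad], T2[bad], T3[bad]); e2 <- c(T2[bad], T3[bad], T1[bad])
    key <- pmin(e1, e2) * (nvirt + 1) + pmax(e1, e2)
    keep <- !(key %in% key[duplicated(key)])
    e1 <- e1[keep]; e2 <- e2[keep]
    alive[bad] <- FALSE
    free <- c(free, bad)
    m <- length(e1)
    take <- min(length(free), m)
    slots <- if (take > 0) free[seq_len(take)] else integer(0)
    if (take > 0) free <- free[-seq_len(take)]
    need <- m - take
    if (need > 0) {
      if (ntri + need > cap) {
        grow <- cap
        T1 <- c(T1, integer(grow)); T2 <- c(T2, integer(grow)); T3 <- c(T3, integer(grow))
        CX <- c(CX, numeric(grow)); CY <- c(CY, numeric(grow)); R2 <- c(R2, numeric(grow))
        alive <- c(alive, logical(grow)); cap <- cap + grow
      }
      slots <- c(slots, ntri + seq_len(need))
      ntri <- ntri + need
    }
    T1[slots] <- e1; T2[slots] <- e2; T3[slots] <- pid
    alive[slots] <- TRUE
    cc <- circumcircles(P, cbind(e1, e2, rep(pid, m)))
    CX[slots] <- cc[, 1]; CY[slots] <- cc[, 2]; R2[slots] <- cc[, 3]
  }
  act <- which(alive[seq_len(ntri)])
  tri <- cbind(T1[act], T2[act], T3[act])
  tri <- tri[tri[, 1] > 3L & tri[, 2] > 3L & tri[, 3] > 3L, , drop = FALSE] - 3L
  a <- pts[tri[, 1], , drop = FALSE]; b <- pts[tri[, 2], , drop = FALSE]
  c3 <- pts[tri[, 3], , drop = FALSE]
  ar <- (b[, 1] - a[, 1]) * (c3[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (c3[, 1] - a[, 1])
  sw <- ar < 0
  tmp <- tri[sw, 2]; tri[sw, 2] <- tri[sw, 3]; tri[sw, 3] <- tmp
  tri
}

triangle_quality <- function(pts, tri) {
  a <- pts[tri[, 1], , drop = FALSE]; b <- pts[tri[, 2], , drop = FALSE]
  c3 <- pts[tri[, 3], , drop = FALSE]
  area <- 0.5 * ((b[, 1] - a[, 1]) * (c3[, 2] - a[, 2]) -
                   (b[, 2] - a[, 2]) * (c3[, 1] - a[, 1]))
  e1 <- sqrt(rowSums((b - c3)^2)); e2 <- sqrt(rowSums((a - c3)^2))
  e3 <- sqrt(rowSums((a - b)^2))
  ang <- function(opp, s1, s2) {
    acos(pmin(1, pmax(-1, (s1^2 + s2^2 - opp^2) / (2 * s1 * s2))))
  }
  min_angle <- pmin(ang(e1, e2, e3), ang(e2, e1, e3), ang(e3, e1, e2)) * 180 / pi
  list(area = abs(area), signed_area = area, min_angle = min_angle)
}

smooth_interior <- function(pts, tri, nfix) {
  ed <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  ed <- rbind(ed, ed[, 2:1])
  sx <- rowsum(pts[ed[, 2], 1], ed[, 1])
  sy <- rowsum(pts[ed[, 2], 2], ed[, 1])
  cnt <- rowsum(rep(1, nrow(ed)), ed[, 1])
  ids <- as.integer(rownames(sx))
  mv <- ids > nfix
  pts[ids[mv], 1] <- sx[mv] / cnt[mv]
  pts[ids[mv], 2] <- sy[mv] / cnt[mv]
  pts
}

# greedy minimum-spacing filter: keep candidates at distance >= h from every
# existing vertex and every earlier accepted candidate
filter_spaced <- function(cand, pts, h) {
  if (!nrow(cand)) return(cand)
  h2 <- h^2
  keep <- logical(nrow(cand))
  acc <- matrix(0, 0, 2)
  for (i in seq_len(nrow(cand))) {
    d2 <- (pts[, 1] - cand[i, 1])^2 + (pts[, 2] - cand[i, 2])^2
    if (min(d2) < h2) next
    if (nrow(acc)) {
      da <- (acc[, 1] - cand[i, 1])^2 + (acc[, 2] - cand[i, 2])^2
      if (min(da) < h2) next
    }
    keep[i] <- TRUE
    acc <- rbind(acc, cand[i, , drop = FALSE])
  }
  cand[keep, , drop = FALSE]
}

# insertion points for violating triangles: circumcenter when safely interior,
# otherwise centroid (always inside, guarantees progress on area splits)
steiner_points <- function(pts, tri, bad, bd_polygon) {
  t <- tri[bad, , drop = FALSE]
  cc <- circumcircles(pts, t)
  cen <- cbind((pts[t[, 1], 1] + pts[t[, 2], 1] + pts[t[, 3], 1]) / 3,
               (pts[t[, 1], 2] + pts[t[, 2], 2] + pts[t[, 3], 2]) / 3)
  ccp <- cc[, 1:2, drop = FALSE]
  margin <- sqrt(pmax(cc[, 3], 0)) * 0.25
  ok <- point_in_polygon(ccp, bd_polygon) &
    dist_to_polygon(ccp, bd_polygon) > margin
  np <- cen
  np[ok, ] <- ccp[ok, , drop = FALSE]
  np
}

#' Calibrate the area bound to reach a target element count
#'
#' Searches (by bracketing and bisection on the area bound, starting from
#' ellipse area / target) for an `a` whose mesh has an element count within
#' 10% of `target_elements`. The search is deterministic: the same ellipse
#' and target always return the same bound.
#'
#' @param ellipse An [ellipse()].
#' @param target_elements Desired number of mesh triangles (>= 10).
#' @param angle_bound Minimum-angle bound passed to [triangulate()].
#' @param tol Relative tolerance on the element count (default 0.1).
#' @param max_iter Maximum number of meshings during the search.
#' @return The calibrated area bound (numeric scalar) with attributes
#'   `n_elements` (the achieved count) and `iterations`.
#' @export
calibrate_area_bound <- function(ellipse, target_elements, angle_bound = 25,
                                 tol = 0.1, max_iter = 30) {
  stopifnot(inherits(ellipse, "ellipse"))
  if (target_elements < 10) rlang::abort("target_elements must be at least 10")
  count_at <- function(a) {
    sub <- subdivide_boundary(ellipse, equilateral_side(a))
    nrow(triangulate(build_pslg(sub, ellipse), a, angle_bound)$triangles)
  }
  a <- ellipse_area(ellipse) / target_elements
  n_used <- 1L
  cnt <- count_at(a)
  ok <- function(cnt) abs(cnt - target_elements) <= tol * target_elements
  if (ok(cnt)) return(structure(a, n_elements = cnt, iterations = n_used))
  # element count decreases as a grows; bracket the target
  lo <- a; hi <- a; clo <- cnt; chi <- cnt
  while (clo < target_elements && n_used < max_iter) {
    lo <- lo / 1.8; clo <- count_at(lo); n_used <- n_used + 1L
    if (ok(clo)) return(structure(lo, n_elements = clo, iterations = n_used))
  }
  while (chi > target_elements && n_used < max_iter) {
    hi <- hi * 1.8; chi <- count_at(hi); n_used <- n_used + 1L
    if (ok(chi)) return(structure(hi, n_elements = chi, iterations = n_used))
  }
  while (n_used < max_iter) {
    mid <- sqrt(lo * hi)
    cmid <- count_at(mid); n_used <- n_used + 1L
    if (ok(cmid)) return(structure(mid, n_elements = cmid, iterations = n_used))
    if (cmid > target_elements) lo <- mid else hi <- mid
  }
  rlang::abort(sprintf(
    "area-bound calibration did not reach within %.0f%% of %d elements in %d meshings",
    100 * tol, target_elements, max_iter))
}

#' Mesh the average ellipse in one call
#'
#' Convenience wrapper chaining [equilateral_side()], [subdivide_boundary()],
#' [build_pslg()] and [triangulate()]. Exactly one of `area_bound` and
#' `target_elements` must be given; with `target_elements` the bound is found
#' by [calibrate_area_bound()].
#'
#' @param ellipse An [ellipse()].
#' @param area_bound Maximum triangle area (square pixels).
#' @param target_elements Desired element count (alternative to `area_bound`).
#' @param angle_bound Minimum interior angle, degrees (default 25).
#' @return A `tri_mesh` whose `subdivision` field holds the boundary
#'   subdivision (the radial angles reused for per-image deformation).
#' @export
mesh_ellipse <- function(ellipse, area_bound = NULL, target_elements = NULL,
                         angle_bound = 25) {
  if (is.null(area_bound) == is.null(target_elements)) {
    rlang::abort("give exactly one of area_bound and target_elements")
  }
  if (is.null(area_bound)) {
    area_bound <- as.numeric(calibrate_area_bound(ellipse, target_elements, angle_bound))
  }
  sub <- subdivide_boundary(ellipse, equilateral_side(area_bound))
  mesh <- triangulate(build_pslg(sub, ellipse), area_bound, angle_bound)
  mesh$subdivision <- sub
  mesh$ellipse <- ellipse
  mesh
}

#' @export
print.tri_mesh <- function(x, ...) {
  q <- triangle_quality(x$vertices, x$triangles)
  cat(sprintf("<tri_mesh> %d vertices, %d triangles (%d boundary vertices)\n",
              nrow(x$vertices), nrow(x$triangles), length(x$boundary_vertex_ids)))
  cat(sprintf("  min angle %.2f deg (bound %g), max area %.3f (bound %g)\n",
              min(q$min_angle), x$angle_bound, max(q$area), x$area_bound))
  invisible(x)
}

#' Per-triangle summary of a mesh
#'
#' @param x A `tri_mesh`.
#' @param ... Unused.
#' @return A tibble with one row per triangle: vertex indices, centroid,
#'   area and minimum interior angle.
#' @method tidy tri_mesh
#' @export
tidy.tri_mesh <- function(x, ...) {
  q <- triangle_quality(x$vertices, x$triangles)
  tibble::tibble(
    element = seq_len(nrow(x$triangles)),
    v1 = x$triangles[, 1], v2 = x$triangles[, 2], v3 = x$triangles[, 3],
    cx = (x$vertices[x$triangles[, 1], 1] + x$vertices[x$triangles[, 2], 1] +
            x$vertices[x$triangles[, 3], 1]) / 3,
    cy = (x$vertices[x$triangles[, 1], 2] + x$vertices[x$triangles[, 2], 2] +
            x$vertices[x$triangles[, 3], 2]) / 3,
    area = q$area, min_angle = q$min_angle)
}

#' One-row summary of a mesh
#'
#' @param x A `tri_mesh`.
#' @param ... Unused.
#' @return A one-row tibble with counts and quality extremes.
#' @method glance tri_mesh
#' @export
glance.tri_mesh <- function(x, ...) {
  q <- triangle_quality(x$vertices, x$triangles)
  tibble::tibble(n_vertices = nrow(x$vertices), n_triangles = nrow(x$triangles),
                 n_boundary = length(x$boundary_vertex_ids),
                 min_angle = min(q$min_angle), max_area = max(q$area),
                 area_bound = x$area_bound, angle_bound = x$angle_bound)
}

# undirected unique edges of a mesh (used for Euler checks and adjacency)
mesh_edges <- function(mesh) {
  tri <- mesh$triangles
  ed <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  unique_rows(ed[order(ed[, 1], ed[, 2]), , drop = FALSE])
}

# element adjacency: pairs of triangles sharing an edge
element_adjacency <- function(mesh) {
  tri <- mesh$triangles
  nt <- nrow(tri)
  ed <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  owner <- rep(seq_len(nt), 3L)
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  sp <- split(owner, key)
  pairs <- sp[lengths(sp) == 2L]
  if (!length(pairs)) return(matrix(integer(0), 0, 2))
  do.call(rbind, lapply(pairs, function(p) sort(p)))
}
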