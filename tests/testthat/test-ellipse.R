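test_that("ellipse constructor validates axes and wraps rotation", {
  expect_error(ellipse(0, 0, 2, 3), "a >= b")
  expect_error(ellipse(0, 0, 1, 0), "a >= b")
  e <- ellipse(0, 0, 3, 1, theta = pi / 2)  # pi-periodic: wraps to -pi/2
  expect_equal(e$theta, -pi / 2)
  expect_equal(ellipse(0, 0, 3, 1, theta = 0.3 + pi)$theta, 0.3)
})

test_that("arc_point lies on the conic for arbitrary rotated ellipses", {
  e <- ellipse(12.5, -3, 40, 17, theta = 0.7)
  expect_equal(as.numeric(arc_point(ellipse(0, 0, 4, 2), 0)), c(4, 0))
  expect_equal(as.numeric(arc_point(ellipse(0, 0, 4, 2), pi / 2)),
               c(0, 2), tolerance = 1e-12)
  ang <- seq(-7, 7, length.out = 41)
  res <- embryomesh:::conic_residual(e, arc_point(e, ang))
  expect_lt(max(abs(res)), 1e-10)
})

test_that("boundary extraction returns the rectangle perimeter and errors on bad masks", {
  rect <- matrix(FALSE, 20, 30)
  rect[5:15, 4:25] <- TRUE  # 11 x 22 pixels
  b <- extract_boundary(rect)
  expect_equal(nrow(b), 2 * (22 + 11) - 4)
  # every boundary pixel has a 4-connected background neighbor
  expect_true(all(b$x %in% (c(4:25) - 0.5)) && all(b$y %in% (c(5:15) - 0.5)))
  expect_gt(embryomesh:::polygon_signed_area(b$x, b$y), 0)
  expect_error(extract_boundary(matrix(FALSE, 5, 5)), "empty")
  two <- rect; two[1, 1] <- TRUE
  expect_error(extract_boundary(two), "exactly one")
})

test_that("boundary of a rasterized disc stays within one pixel of the circle", {
  m <- disc_mask(20)
  b <- extract_boundary(m)
  r <- sqrt((b$x - 25)^2 + (b$y - 25)^2)
  expect_true(all(abs(r - 20) <= 1))
  # boundary is a connected pixel ring in trace order
  dx <- abs(diff(b$x)); dy <- abs(diff(b$y))
  expect_true(all(dx <= 1 & dy <= 1))
})

test_that("direct least-squares fit recovers noiseless ellipses to 1e-6", {
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  e0 <- ellipse(50, 40, 40, 20)
  pts <- arc_point(e0, th)
  f <- fit_ellipse(pts)
  expect_equal(f$cx, 50, tolerance = 1e-6)
  expect_equal(f$cy, 40, tolerance = 1e-6)
  expect_equal(f$a, 40, tolerance = 1e-6)
  expect_equal(f$b, 20, tolerance = 1e-6)
  expect_lt(abs(f$theta), 1e-6)
  # unit circle: both semi-axes 1
  circ <- fit_ellipse(cbind(cos(th), sin(th)))
  expect_equal(circ$a, 1, tolerance = 1e-9)
  expect_equal(circ$b, 1, tolerance = 1e-9)
  expect_error(fit_ellipse(pts[1:4, ]), "at least 5")
  expect_error(fit_ellipse(cbind(1:10, 2 * (1:10) + 3)), "degenerate|ellipse")
})

test_that("algebraic fit agrees with a geometric (Sampson) oracle under noise", {
  set.seed(31)
  th <- seq(0, 2 * pi, length.out = 201)[-201]
  e0 <- ellipse(50, 40, 40, 20, theta = 0.3)
  pts <- arc_point(e0, th) + matrix(rnorm(400, sd = 0.5), ncol = 2)
  f <- fit_ellipse(pts)
  g <- sampson_fit_oracle(pts[, 1], pts[, 2], f)
  expect_lt(abs(f$cx - g$cx), 0.2)
  expect_lt(abs(f$cy - g$cy), 0.2)
  expect_lt(abs(f$a - g$a), 0.3)
  expect_lt(abs(f$b - g$b), 0.3)
  expect_lt(abs(f$theta - g$theta), 0.02)
})

test_that("fitting is equivariant under translation and rotation of the points", {
  th <- seq(0, 2 * pi, length.out = 121)[-121]
  e0 <- ellipse(0, 0, 30, 12, theta = 0.2)
  pts <- arc_point(e0, th)
  phi <- 0.5; tr <- c(7, -4)
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  moved <- t(R %*% t(pts)) + matrix(tr, nrow(pts), 2, byrow = TRUE)
  f <- fit_ellipse(moved)
  expect_equal(f$a, 30, tolerance = 1e-6)
  expect_equal(f$b, 12, tolerance = 1e-6)
  expect_equal(c(f$cx, f$cy), as.numeric(R %*% c(0, 0) + tr), tolerance = 1e-6)
  expect_equal(f$theta, embryomesh:::wrap_half_pi(0.2 + phi), tolerance = 1e-6)
})

test_that("ellipse averaging is idempotent, linear in axes, circular in rotation", {
  e <- ellipse(10, 20, 40, 20, theta = 0.1)
  expect_equal(average_ellipses(list(e, e, e)), e)
  avg <- average_ellipses(list(ellipse(0, 0, 40, 20), ellipse(0, 0, 60, 20)))
  expect_equal(avg$a, 50)
  expect_equal(avg$b, 20)
  # rotations +0.1 and -0.1 average to 0 via the doubled-angle circular mean
  rot <- average_ellipses(list(ellipse(0, 0, 4, 2, 0.1), ellipse(0, 0, 4, 2, -0.1)))
  expect_equal(rot$theta, 0, tolerance = 1e-12)
  # near the +/- pi/2 branch cut the naive arithmetic mean would be wrong
  rot2 <- average_ellipses(list(ellipse(0, 0, 4, 2, pi / 2 - 0.05),
                                ellipse(0, 0, 4, 2, -pi / 2 + 0.05)))
  expect_equal(abs(rot2$theta), pi / 2, tolerance = 1e-12)
  # permutation invariance
  es <- list(ellipse(1, 2, 30, 10, 0.2), ellipse(3, 1, 35, 15, -0.1),
             ellipse(-2, 0, 28, 12, 0.4))
  expect_equal(average_ellipses(es), average_ellipses(rev(es)))
  expect_error(average_ellipses(list()), "empty")
})
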