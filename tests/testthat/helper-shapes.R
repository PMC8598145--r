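# Shared test fixtures and independent oracles, built in code.

# random simple convex polygon: convex hull of points scattered in a box
random_convex_polygon <- function(n_points = 12, scale = NULL, center = NULL) {
  scale <- scale %||% runif(1, 2, 7)
  center <- center %||% runif(2, -3, 3)
  x <- runif(n_points, 0, scale) + center[1]
  y <- runif(n_points, 0, scale) + center[2]
  h <- grDevices::chull(x, y)
  polygon2d(x[h], y[h])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force largest-inscribed-circle oracle: dense grid over the bounding
# box, keep interior points, maximize the minimum distance to any edge
grid_inscribed_diameter <- function(poly, pitch = 0.025) {
  xr <- range(poly$x); yr <- range(poly$y)
  gx <- seq(xr[1], xr[2], by = pitch)
  gy <- seq(yr[1], yr[2], by = pitch)
  g <- expand.grid(x = gx, y = gy)
  inside <- insertfactor:::points_in_polygon(g$x, g$y, poly)
  if (!any(inside)) return(0)
  d <- insertfactor:::dist_to_boundary(g$x[inside], g$y[inside], poly)
  2 * max(d)
}

# closed-form area of the regular n-gon inscribed in a circle of radius R
regular_ngon_area <- function(n, R) n * R^2 * sin(2 * pi / n) / 2

# numerical-quadrature ellipse perimeter (independent of Ramanujan)
ellipse_perimeter_quadrature <- function(width, length) {
  a <- length / 2; b <- width / 2
  f <- function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2)
  4 * stats::integrate(f, 0, pi / 2, rel.tol = 1e-10)$value
}

# standard A10 context used across tests
a10_context <- function() beam_context("synthetic", 12, 10, 100)

# rigid motion of a polygon (for invariance tests)
rot_shift_poly <- function(p, angle, shift) {
  polygon2d(p$x * cos(angle) - p$y * sin(angle) + shift[1],
            p$x * sin(angle) + p$y * cos(angle) + shift[2])
}
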