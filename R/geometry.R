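#' Construct a cutout polygon
#'
#' A `polygon2d` is a simple (non-self-intersecting) closed polygon in the
#' beam's-eye-view plane at 100 cm source distance, with vertices in cm.
#' The first vertex is implicitly joined to the last; a trailing duplicate
#' of the first vertex is dropped and consecutive duplicate vertices are
#' merged (tolerance 1e-9 cm). Orientation is irrelevant: all downstream
#' quantities use the absolute enclosed area.
#'
#' Multiply-connected cutouts (island blocks, holes) are not representable
#' and polygons whose edges cross are rejected.
#'
#' @param x,y numeric vectors of vertex coordinates (cm), or `x` may be a
#'   two-column matrix/data frame with `y` missing.
#' @return An object of class `polygon2d`: a list with numeric vectors
#'   `x` and `y`.
#' @examples
#' sq <- polygon2d(c(0, 4, 4, 0), c(0, 0, 4, 4))
#' polygon_area(sq)
#' @export
polygon2d <- function(x, y = NULL) {
  if (is.null(y)) {
    m <- as.matrix(x)
    stop_if(ncol(m) < 2, "polygon2d: need two coordinate columns",
            class = "invalid_shape")
    x <- as.numeric(m[, 1]); y <- as.numeric(m[, 2])
  }
  stop_if(length(x) != length(y), "polygon2d: x and y lengths differ",
          class = "invalid_shape")
  stop_if(anyNA(x) || anyNA(y) || any(!is.finite(c(x, y))),
          "polygon2d: non-finite vertex coordinates", class = "invalid_shape")
  # drop trailing duplicate of the first vertex, merge consecutive duplicates
  n <- length(x)
  if (n > 1 && abs(x[n] - x[1]) < 1e-9 && abs(y[n] - y[1]) < 1e-9) {
    x <- x[-n]; y <- y[-n]
  }
  keep <- c(TRUE, abs(diff(x)) > 1e-9 | abs(diff(y)) > 1e-9)
  x <- x[keep]; y <- y[keep]
  stop_if(length(x) < 3, "polygon2d: fewer than 3 distinct vertices",
          class = "invalid_shape")
  p <- structure(list(x = x, y = y), class = "polygon2d")
  stop_if(abs(signed_area(p)) < 1e-12, "polygon2d: zero enclosed area",
          class = "invalid_shape")
  stop_if(polygon_self_intersects(p), "polygon2d: edges self-intersect",
          class = "invalid_shape")
  p
}

#' @export
print.polygon2d <- function(x, ...) {
  cat(sprintf("<polygon2d: %d vertices, area %.4f cm^2>\n",
              length(x$x), polygon_area(x)))
  invisible(x)
}

as_polygon2d <- function(p) {
  if (inherits(p, "polygon2d")) p else polygon2d(p)
}

signed_area <- function(poly) {
  x <- poly$x; y <- poly$y
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# O(n^2) segment-crossing test; adjacent edges share endpoints and are skipped.
polygon_self_intersects <- function(poly) {
  x <- poly$x; y <- poly$y; n <- length(x)
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    if (i == 1) js <- js[js != n]  # edge n closes back onto edge 1
    for (j in js) {
      d1 <- cross(x[i], y[i], xn[i], yn[i], x[j], y[j])
      d2 <- cross(x[i], y[i], xn[i], yn[i], xn[j], yn[j])
      d3 <- cross(x[j], y[j], xn[j], yn[j], x[i], y[i])
      d4 <- cross(x[j], y[j], xn[j], yn[j], xn[i], yn[i])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Polygon area by the shoelace formula
#'
#' @param poly a [polygon2d()] (or coercible coordinate matrix).
#' @return Enclosed area in cm^2 (absolute value; independent of vertex
#'   ordering direction and of translation).
#' @export
polygon_area <- function(poly) {
  abs(signed_area(as_polygon2d(poly)))
}

#' Polygon perimeter
#'
#' @inheritParams polygon_area
#' @return Perimeter in cm.
#' @export
polygon_perimeter <- function(poly) {
  poly <- as_polygon2d(poly)
  x <- poly$x; y <- poly$y
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

# Vectorized even-odd point-in-polygon (points on an edge are resolved
# arbitrarily; callers needing boundary behaviour use distances instead).
points_in_polygon <- function(px, py, poly) {
  x <- poly$x; y <- poly$y; n <- length(x)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (y[j] > py)) &
      (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Minimum distance from points to the polygon boundary (all edges),
# vectorized over points.
dist_to_boundary <- function(px, py, poly) {
  x <- poly$x; y <- poly$y; n <- length(x)
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  d2 <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    ex <- xn[i] - x[i]; ey <- yn[i] - y[i]
    len2 <- ex * ex + ey * ey
    t <- ((px - x[i]) * ex + (py - y[i]) * ey) / len2
    t <- pmin(1, pmax(0, t))
    dx <- px - (x[i] + t * ex); dy <- py - (y[i] + t * ey)
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

# Signed distance: positive inside, negative outside.
signed_dist <- function(px, py, poly) {
  d <- dist_to_boundary(px, py, poly)
  ifelse(points_in_polygon(px, py, poly), d, -d)
}

#' Largest circle fully enclosed by a polygon
#'
#' Finds the interior point maximizing the distance to the polygon boundary
#' (the "pole of inaccessibility") by iterative grid refinement: a coarse
#' grid over the bounding box is scored by signed boundary distance, cells
#' that could still beat the current best (center distance plus cell
#' circumradius) are subdivided, and refinement stops once the cell size
#' guarantees the requested accuracy. Robust for the non-convex shapes that
#' occur in clinical cutouts; no solver dependency.
#'
#' @inheritParams polygon_area
#' @param tol accuracy of the returned diameter, cm (default 0.005).
#' @return A list with `center` (numeric length 2, cm) and `diameter` (cm).
#' @examples
#' largest_inscribed_circle(rectangle_polygon(5, 17))$diameter  # 5
#' @export
largest_inscribed_circle <- function(poly, tol = 0.005) {
  poly <- as_polygon2d(poly)
  stop_if(!is_number(tol) || tol <= 0, "tol must be a positive number",
          class = "invalid_argument")
  xr <- range(poly$x); yr <- range(poly$y)
  wid <- diff(xr); hei <- diff(yr)
  size <- max(min(wid, hei) / 8, max(wid, hei) / 64)
  cx <- seq(xr[1] + size / 2, xr[2], by = size)
  cy <- seq(yr[1] + size / 2, yr[2], by = size)
  g <- expand.grid(x = cx, y = cy)
  px <- g$x; py <- g$y
  # seed with the centroid so thin shapes never start empty-handed
  px <- c(px, mean(poly$x)); py <- c(py, mean(poly$y))
  best_d <- -Inf; best_xy <- c(mean(xr), mean(yr))
  repeat {
    d <- signed_dist(px, py, poly)
    i <- which.max(d)
    if (d[i] > best_d) {
      best_d <- d[i]; best_xy <- c(px[i], py[i])
    }
    if (size * sqrt(2) < tol) break
    keep <- d + size / sqrt(2) > best_d + tol / 8
    if (!any(keep)) break
    px <- px[keep]; py <- py[keep]
    size <- size / 2
    off <- size / 2
    px <- c(px - off, px - off, px + off, px + off)
    py <- c(py - off, py + off, py - off, py + off)
  }
  stop_if(best_d <= 0, "no interior point found; degenerate polygon",
          class = "invalid_shape")
  list(center = best_xy, diameter = 2 * best_d)
}

#' Ramanujan approximation to an ellipse perimeter
#'
#' Ramanujan's first approximation,
#' \eqn{P \approx \pi[3(a+b) - \sqrt{(3a+b)(a+3b)}]}, with semi-axes
#' `a = length/2`, `b = width/2`. Sub-0.05% error at clinical aspect
#' ratios; used so the perimeter-to-area axis of the spline model is
#' reproducible bit-for-bit.
#'
#' @param width,length full ellipse axes, cm.
#' @return Perimeter, cm.
#' @export
ellipse_perimeter <- function(width, length) {
  a <- length / 2; b <- width / 2
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

#' Parameterize a cutout shape as its equivalent ellipse
#'
#' The equivalent ellipse of an insert shape has width equal to the
#' diameter of the largest circle fully enclosed by the shape, and length
#' set so that the ellipse area equals the shape area
#' (`length = 4 * area / (pi * width)`). The perimeter-to-area ratio of
#' this ellipse (Ramanujan perimeter over area) is the second coordinate
#' of the spline parameter space. All outputs are invariant under
#' translation and rigid rotation of the polygon (to within `tol`).
#'
#' @inheritParams largest_inscribed_circle
#' @return An object of class `equivalent_ellipse`: list with `width_cm`,
#'   `length_cm`, `area_cm2`, `pa_ratio_per_cm`.
#' @examples
#' parameterize_shape(rectangle_polygon(4, 4))  # width 4, length 16/pi
#' @export
parameterize_shape <- function(poly, tol = 0.005) {
  poly <- as_polygon2d(poly)
  area <- polygon_area(poly)
  width <- largest_inscribed_circle(poly, tol = tol)$diameter
  len <- 4 * area / (pi * width)
  equivalent_ellipse(width, len)
}

#' Construct an equivalent ellipse from width and length
#'
#' @param width_cm,length_cm full ellipse axes, cm (`length_cm` defaults to
#'   `width_cm`, i.e. a circle).
#' @return An `equivalent_ellipse` object.
#' @export
equivalent_ellipse <- function(width_cm, length_cm = width_cm) {
  stop_if(!is_number(width_cm) || width_cm <= 0, "width must be positive",
          class = "invalid_shape")
  stop_if(!is_number(length_cm) || length_cm < width_cm * (1 - 1e-9),
          "length must be >= width (inscribed-circle area cannot exceed shape area)",
          class = "invalid_shape")
  area <- pi * (width_cm / 2) * (length_cm / 2)
  structure(list(
    width_cm = width_cm,
    length_cm = length_cm,
    area_cm2 = area,
    pa_ratio_per_cm = ellipse_perimeter(width_cm, length_cm) / area
  ), class = "equivalent_ellipse")
}

#' @export
print.equivalent_ellipse <- function(x, ...) {
  cat(sprintf(
    "<equivalent_ellipse: width %.3f cm, length %.3f cm, area %.3f cm^2, P/A %.4f /cm>\n",
    x$width_cm, x$length_cm, x$area_cm2, x$pa_ratio_per_cm))
  invisible(x)
}
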