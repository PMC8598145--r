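#' Regular-polygon approximations of standard insert shapes
#'
#' Circles, ellipses and rectangles are the shapes used both for model
#' input measurements and for clinical standard inserts. Curved shapes are
#' represented as dense regular polygons (default 128 vertices), which
#' keeps the discretization error of the area and of the inscribed-circle
#' diameter below 0.1% at clinical sizes.
#'
#' @param diameter circle diameter, cm.
#' @param width,length full ellipse axes (cm); `width <= length` is not
#'   required here (axes are symmetric).
#' @param n number of polygon vertices for curved shapes.
#' @param center numeric length-2 center offset, cm.
#' @param angle rigid rotation of the shape, radians.
#' @return A [polygon2d()].
#' @name standard_shapes
NULL

#' @rdname standard_shapes
#' @export
circle_polygon <- function(diameter, n = 128, center = c(0, 0)) {
  ellipse_polygon(diameter, diameter, n = n, center = center)
}

#' @rdname standard_shapes
#' @export
ellipse_polygon <- function(width, length, n = 128, center = c(0, 0), angle = 0) {
  stop_if(!is_number(width) || !is_number(length) || width <= 0 || length <= 0,
          "ellipse axes must be positive", class = "invalid_argument")
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- (width / 2) * cos(th); y <- (length / 2) * sin(th)
  rot_shift(x, y, angle, center)
}

#' @rdname standard_shapes
#' @export
rectangle_polygon <- function(width, length, center = c(0, 0), angle = 0) {
  stop_if(!is_number(width) || !is_number(length) || width <= 0 || length <= 0,
          "rectangle sides must be positive", class = "invalid_argument")
  x <- c(-1, 1, 1, -1) * width / 2
  y <- c(-1, -1, 1, 1) * length / 2
  rot_shift(x, y, angle, center)
}

rot_shift <- function(x, y, angle, center) {
  if (angle != 0) {
    xr <- x * cos(angle) - y * sin(angle)
    yr <- x * sin(angle) + y * cos(angle)
    x <- xr; y <- yr
  }
  polygon2d(x + center[1], y + center[2])
}

#' Read or write a plain-text polygon file
#'
#' One `x,y` vertex pair (cm) per line; blank lines and `#` comments are
#' ignored.
#'
#' @param path file path.
#' @param poly a [polygon2d()].
#' @return `read_polygon` returns a [polygon2d()]; `write_polygon` returns
#'   `path` invisibly.
#' @export
read_polygon <- function(path) {
  stop_if(!file.exists(path), "polygon file not found: ", path,
          class = "io_error")
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  stop_if(length(ln) < 3, "polygon file has fewer than 3 vertices: ", path,
          class = "invalid_shape")
  parts <- strsplit(ln, "[,[:space:]]+")
  bad <- which(vapply(parts, length, 1L) < 2)
  stop_if(length(bad) > 0, "malformed vertex line in ", path, " (line ", bad[1], ")",
          class = "parse_error")
  x <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1)))
  y <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  stop_if(anyNA(x) || anyNA(y), "non-numeric vertex in ", path,
          class = "parse_error")
  polygon2d(x, y)
}

#' @rdname read_polygon
#' @export
write_polygon <- function(poly, path) {
  poly <- as_polygon2d(poly)
  writeLines(
    c("# cutout polygon, x,y in cm at 100 cm source distance",
      sprintf("%.9g,%.9g", poly$x, poly$y)),
    path)
  invisible(path)
}
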