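test_that("shoelace area matches closed forms and is invariant to pose", {
  expect_equal(polygon_area(polygon2d(c(0, 1, 1, 0), c(0, 0, 1, 1))), 1.0)
  expect_equal(polygon_area(rectangle_polygon(4, 4)), 16.0)

  # 128-gon approximating a circle of diameter 8: regular-polygon area
  cp <- circle_polygon(8, n = 128)
  expect_equal(polygon_area(cp), regular_ngon_area(128, 4), tolerance = 1e-12)
  expect_equal(polygon_area(cp), pi * 16, tolerance = 1e-3)

  # ordering direction, translation and rotation leave the area unchanged
  p <- rectangle_polygon(3, 7)
  rev_p <- polygon2d(rev(p$x), rev(p$y))
  expect_equal(polygon_area(rev_p), 21)
  moved <- rot_shift_poly(p, angle = 0.7, shift = c(12, -4))
  expect_equal(polygon_area(moved), 21, tolerance = 1e-12)
})

test_that("degenerate and self-intersecting polygons are rejected", {
  expect_error(polygon2d(c(0, 1), c(0, 0)), class = "invalid_shape")
  expect_error(polygon2d(c(0, 1, 2), c(0, 0, 0)), class = "invalid_shape")  # collinear
  # bow-tie
  expect_error(polygon2d(c(0, 1, 0, 1), c(0, 1, 1, 0)), class = "invalid_shape")
})

test_that("closure duplicates and consecutive duplicates are normalized", {
  p <- polygon2d(c(0, 4, 4, 4, 0, 0), c(0, 0, 0, 4, 4, 0))
  expect_length(p$x, 4)
  expect_equal(polygon_area(p), 16)
})

test_that("largest inscribed circle matches geometry and a grid oracle", {
  # a circle's largest enclosed circle is itself
  lic <- largest_inscribed_circle(circle_polygon(6, n = 256))
  expect_equal(lic$diameter, 6, tolerance = 0.01)

  # rectangle: inscribed diameter equals the short side
  expect_equal(largest_inscribed_circle(rectangle_polygon(5, 17))$diameter,
               5, tolerance = 0.005)

  # ellipse 5 x 10: inscribed diameter equals the minor axis; cross-check
  # against the brute-force grid oracle at 0.01 cm pitch
  ep <- ellipse_polygon(5, 10, n = 256)
  d <- largest_inscribed_circle(ep)$diameter
  expect_equal(d, 5, tolerance = 0.01)
  expect_equal(d, grid_inscribed_diameter(ep, pitch = 0.01),
               tolerance = 2 * 0.005 + 0.01)
})

test_that("inscribed circle agrees with the grid oracle on random convex polygons", {
  set.seed(101)
  for (i in 1:12) {
    poly <- random_convex_polygon()
    d <- largest_inscribed_circle(poly)$diameter
    expect_equal(d, grid_inscribed_diameter(poly, pitch = 0.025),
                 tolerance = 2 * 0.005 + 0.025)
  }
})

test_that("inscribed circle is pose-invariant within tolerance", {
  set.seed(7)
  poly <- random_convex_polygon()
  d0 <- largest_inscribed_circle(poly)$diameter
  for (k in 1:3) {
    moved <- rot_shift_poly(poly, angle = runif(1, 0, 2 * pi),
                            shift = runif(2, -10, 10))
    expect_equal(largest_inscribed_circle(moved)$diameter, d0,
                 tolerance = 2 * 0.005)
  }
})

test_that("Ramanujan perimeter tracks quadrature to well under 0.05%", {
  for (ab in list(c(4, 4), c(4, 8), c(3, 12), c(2.5, 13), c(5, 10))) {
    expect_equal(ellipse_perimeter(ab[1], ab[2]),
                 ellipse_perimeter_quadrature(ab[1], ab[2]),
                 tolerance = 5e-4)
  }
})

test_that("equivalent ellipse reproduces closed-form parameterizations", {
  # a circle maps to itself
  ce <- parameterize_shape(circle_polygon(8, n = 256))
  expect_equal(ce$width_cm, 8, tolerance = 8 * 0.005)
  expect_equal(ce$length_cm, 8, tolerance = 8 * 0.005)

  # 4x4 square: inscribed diameter 4, length from area equivalence
  se <- parameterize_shape(rectangle_polygon(4, 4))
  expect_equal(se$width_cm, 4, tolerance = 0.005)
  expect_equal(se$length_cm, 16 / pi, tolerance = 0.01)

  # an ellipse maps to itself
  ee <- parameterize_shape(ellipse_polygon(5, 10, n = 256))
  expect_equal(ee$width_cm, 5, tolerance = 5 * 0.005)
  expect_equal(ee$length_cm, 10, tolerance = 10 * 0.005)
})

test_that("parameterization invariants hold on random polygons", {
  set.seed(202)
  for (i in 1:15) {
    poly <- random_convex_polygon()
    ee <- parameterize_shape(poly)
    # inscribed-circle area cannot exceed the polygon area
    expect_gte(ee$length_cm, ee$width_cm * (1 - 1e-9))
    # length is defined from exact area equivalence
    expect_equal(pi * (ee$width_cm / 2) * (ee$length_cm / 2),
                 polygon_area(poly), tolerance = 1e-9)
    expect_gt(ee$pa_ratio_per_cm, 0)
  }
})

test_that("parameterization is invariant under rigid motion", {
  poly <- ellipse_polygon(4, 9, n = 128)
  e0 <- parameterize_shape(poly)
  moved <- rot_shift_poly(poly, angle = 1.1, shift = c(-6, 3))
  e1 <- parameterize_shape(moved)
  expect_equal(e1$width_cm, e0$width_cm, tolerance = 0.01)
  expect_equal(e1$length_cm, e0$length_cm, tolerance = 0.02)
  expect_equal(e1$pa_ratio_per_cm, e0$pa_ratio_per_cm, tolerance = 0.005)
})

test_that("polygon text files round-trip and reject malformed input", {
  f <- withr::local_tempfile(fileext = ".txt")
  poly <- ellipse_polygon(3, 8, n = 64)
  write_polygon(poly, f)
  back <- read_polygon(f)
  expect_equal(back$x, poly$x, tolerance = 1e-8)
  expect_equal(back$y, poly$y, tolerance = 1e-8)

  writeLines(c("# comment", "1,1", "not,a,number", "2,2"), f)
  expect_error(read_polygon(f), class = "parse_error")
})
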