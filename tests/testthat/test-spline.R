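scatter_records <- function(n, f, seed = 1, wlim = c(2.5, 9.5),
                            rlim = c(0.4, 1.6)) {
  set.seed(seed)
  w <- runif(n, wlim[1], wlim[2])
  r <- runif(n, rlim[1], rlim[2])
  data.frame(shape_id = sprintf("r%02d", seq_len(n)), width_cm = w,
             pa_ratio_per_cm = r, insert_factor = f(w, r))
}

test_that("a constant factor surface is reproduced everywhere", {
  recs <- scatter_records(9, function(w, r) rep(0.950, length(w)))
  m <- fit_insert_model(recs)
  p <- suppressWarnings(predict_factor(m, width_cm = c(3, 5, 8, 6.2),
                                       pa_ratio_per_cm = c(0.8, 1.2, 0.5, 0.96)))
  expect_equal(p$insert_factor, rep(0.950, 4), tolerance = 1e-9)
})

test_that("the eight-measurement floor is enforced", {
  recs <- scatter_records(7, function(w, r) 0.9 + 0.01 * w)
  expect_error(fit_insert_model(recs), class = "insufficient_data")
  expect_error(fit_insert_model(recs, degrees = c(1, 1)),
               class = "insufficient_data")
})

test_that("linear and representable-quadratic surfaces are exact at s = 0", {
  lin <- function(w, r) 0.9 + 0.01 * w - 0.02 * r
  recs <- scatter_records(10, lin)
  m <- fit_insert_model(recs, smoothing = 0, n_knots = c(0, 0))
  set.seed(5)
  qw <- runif(20, 3.5, 8.5); qr <- runif(20, 0.6, 1.4)
  p <- suppressWarnings(predict_factor(m, width_cm = qw, pa_ratio_per_cm = qr))
  expect_equal(p$insert_factor, lin(qw, qr), tolerance = 1e-6)

  quad <- function(w, r) 0.85 + 0.02 * w - 0.0012 * w^2 - 0.03 * r + 0.001 * w * r
  recs2 <- scatter_records(12, quad, seed = 3)
  m2 <- fit_insert_model(recs2, smoothing = 0, n_knots = c(0, 0))
  p2 <- suppressWarnings(predict_factor(m2, width_cm = qw, pa_ratio_per_cm = qr))
  expect_equal(p2$insert_factor, quad(qw, qr), tolerance = 1e-6)
})

test_that("an interpolating fit passes through its training points", {
  # degrees (3, 1) with no interior knots: 8 coefficients = 8 points
  recs <- scatter_records(8, function(w, r) 1 - 0.2 * exp(-w / 3) - 0.02 * r,
                          seed = 9)
  m <- fit_insert_model(recs, smoothing = 0, n_knots = c(0, 0))
  p <- suppressWarnings(predict_factor(m, width_cm = recs$width_cm,
                                       pa_ratio_per_cm = recs$pa_ratio_per_cm))
  expect_equal(p$insert_factor, recs$insert_factor, tolerance = 1e-9)
})

test_that("fitting is invariant to record order", {
  recs <- scatter_records(11, function(w, r) 1 - 0.2 * exp(-w / 3) - 0.02 * r)
  m1 <- fit_insert_model(recs)
  set.seed(4)
  m2 <- fit_insert_model(recs[sample(nrow(recs)), ])
  q <- list(w = c(4, 6, 8), r = c(0.7, 1.0, 1.3))
  p1 <- suppressWarnings(predict_factor(m1, width_cm = q$w, pa_ratio_per_cm = q$r))
  p2 <- suppressWarnings(predict_factor(m2, width_cm = q$w, pa_ratio_per_cm = q$r))
  expect_equal(p1$insert_factor, p2$insert_factor, tolerance = 1e-12)
})

test_that("degenerate designs raise classed errors", {
  recs <- scatter_records(9, function(w, r) 0.95 + 0.01 * r)
  recs$width_cm <- 5  # all widths identical
  expect_error(fit_insert_model(recs), class = "degenerate_design")

  mixed <- scatter_records(9, function(w, r) rep(0.95, length(w)))
  mixed$key <- rep(c("a", "b"), length.out = 9)
  expect_error(fit_insert_model(mixed), class = "mixed_groups")
})

test_that("extrapolation is flagged but still evaluated", {
  recs <- scatter_records(10, function(w, r) 0.9 + 0.01 * w - 0.02 * r)
  m <- fit_insert_model(recs, smoothing = 0, n_knots = c(0, 0))
  expect_warning(
    p <- predict_factor(m, width_cm = max(recs$width_cm) + 3,
                        pa_ratio_per_cm = 1),
    "extrapolation")
  expect_true(p$extrapolated)
  # the boundary polynomial is continued exactly for a representable surface
  expect_equal(p$insert_factor, 0.9 + 0.01 * (max(recs$width_cm) + 3) - 0.02,
               tolerance = 1e-6)
  inside <- suppressWarnings(
    predict_factor(m, width_cm = mean(recs$width_cm),
                   pa_ratio_per_cm = mean(recs$pa_ratio_per_cm)))
  expect_false(inside$extrapolated)
})

test_that("leave-one-out needs nine records and is exact on linear surfaces", {
  lin <- function(w, r) 0.9 + 0.01 * w - 0.02 * r
  expect_error(loo_errors(scatter_records(8, lin)), class = "insufficient_data")

  res <- loo_errors(scatter_records(12, lin), smoothing = 0, n_knots = c(0, 0))
  expect_lt(max(abs(res$predicted - res$measured)), 1e-6)

  const <- loo_errors(scatter_records(10, function(w, r) rep(0.95, length(w))))
  expect_equal(const$percent_difference, rep(0, 10), tolerance = 1e-7)
})

test_that("model JSON serialization round-trips exactly", {
  f <- withr::local_tempfile(fileext = ".json")
  recs <- scatter_records(11, function(w, r) 1 - 0.2 * exp(-w / 3) - 0.02 * r)
  recs$key <- "TrueBeam|12|10|100"
  m <- fit_insert_model(recs)
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(m2$key, m$key)
  q <- list(w = seq(3, 9, by = 0.5), r = seq(0.5, 1.5, length.out = 13))
  p1 <- suppressWarnings(predict_factor(m, width_cm = q$w, pa_ratio_per_cm = q$r))
  p2 <- suppressWarnings(predict_factor(m2, width_cm = q$w, pa_ratio_per_cm = q$r))
  expect_equal(p2$insert_factor, p1$insert_factor, tolerance = 1e-12)
  expect_error(load_model(withr::local_tempfile(lines = "{}", fileext = ".json")),
               class = "parse_error")
})

test_that("predict() dispatches on equivalent ellipses and data frames", {
  recs <- scatter_records(10, function(w, r) 0.9 + 0.01 * w - 0.02 * r)
  m <- fit_insert_model(recs, smoothing = 0, n_knots = c(0, 0))
  ee <- equivalent_ellipse(5, 9)
  p1 <- suppressWarnings(predict(m, ee))
  p2 <- suppressWarnings(predict_factor(m, ellipse = ee))
  expect_equal(p1$insert_factor, p2$insert_factor)
})
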