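#' Fit a bivariate spline model of insert factors
#'
#' Fits a least-squares tensor-product polynomial spline to measured
#' insert factors over the (width, perimeter-to-area ratio) plane of the
#' equivalent-ellipse parameterization. One model describes one
#' (machine, energy, applicator, SSD) combination; a minimum of eight
#' measurements is required to create a model, regardless of the degrees
#' chosen. Training coordinates are standardized to unit ranges before
#' fitting (width in cm and P/A in 1/cm differ in scale by roughly an
#' order of magnitude) and interior knots, when the data afford them, are
#' placed at coordinate quantiles. Records are canonically sorted by
#' (width, P/A, shape id) so the fit is independent of input order.
#'
#' @param records data frame of one group of measurements with columns
#'   `width_cm`, `insert_factor`, and either `pa_ratio_per_cm` or
#'   `length_cm` (from which P/A is derived); typically [db_group()]
#'   output.
#' @param degrees spline degrees `c(k_width, k_pa)`; default cubic along
#'   width (the small-field output drop bends the surface strongly in
#'   width) and linear along P/A. The default tensor basis has exactly
#'   `(3 + 1) * (1 + 1) = 8` coefficients, the model's minimum data
#'   requirement.
#' @param smoothing penalty weight `s >= 0` on coefficient differences
#'   along the (standardized) coefficient grid. The default `1e-3` is a
#'   mild regularization that stabilizes the fit in corners of the
#'   parameter plane the bounding designs leave empty; set `s = 0` for
#'   the exact least-squares (or, at 8 points, interpolating) fit.
#' @param n_knots integer vector: interior knot counts along (width, P/A),
#'   or `NULL` to choose automatically from the data size (knots are added
#'   along width only when the group can support the extra coefficients;
#'   at the 8-13 measurements typical here the automatic choice is no
#'   interior knots).
#' @return An object of class `insert_spline`.
#' @seealso [predict_factor()], [loo_errors()], [save_model()]
#' @export
fit_insert_model <- function(records, degrees = c(3, 1), smoothing = 1e-3,
                             n_knots = NULL) {
  records <- as.data.frame(records)
  if (is.null(records$pa_ratio_per_cm)) {
    stop_if(is.null(records$width_cm) || is.null(records$length_cm),
            "records need width_cm plus pa_ratio_per_cm or length_cm",
            class = "invalid_argument")
    records$pa_ratio_per_cm <- vapply(seq_len(nrow(records)), function(i) {
      equivalent_ellipse(records$width_cm[i], records$length_cm[i])$pa_ratio_per_cm
    }, 0)
  }
  key <- if (!is.null(records$key)) unique(records$key) else "unkeyed"
  stop_if(length(key) > 1, "records mix model groups: ",
          paste(key, collapse = "; "), class = "mixed_groups")
  n <- nrow(records)
  stop_if(n < 8, "group ", key, ": ", n,
          " measurements; a spline model requires a minimum of eight",
          class = "insufficient_data")
  stop_if(length(degrees) != 2 || any(degrees < 1),
          "degrees must be two integers >= 1", class = "invalid_argument")
  stop_if(!is_number(smoothing) || smoothing < 0,
          "smoothing must be >= 0", class = "invalid_argument")

  if (is.null(records$shape_id)) records$shape_id <- as.character(seq_len(n))
  ord <- order(records$width_cm, records$pa_ratio_per_cm, records$shape_id)
  records <- records[ord, , drop = FALSE]

  w <- records$width_cm; r <- records$pa_ratio_per_cm; f <- records$insert_factor
  wr <- range(w); rr <- range(r)
  stop_if(diff(wr) <= 0, "degenerate design: all widths identical",
          class = "degenerate_design")
  stop_if(diff(rr) <= 0, "degenerate design: all P/A ratios identical",
          class = "degenerate_design")
  u <- (w - wr[1]) / diff(wr)
  v <- (r - rr[1]) / diff(rr)

  if (is.null(n_knots)) n_knots <- auto_knot_counts(n, degrees)
  knots_u <- clamped_knots(u, degrees[1], n_knots[1])
  knots_v <- clamped_knots(v, degrees[2], n_knots[2])
  Bu <- basis_matrix(u, knots_u, degrees[1])
  Bv <- basis_matrix(v, knots_v, degrees[2])
  B <- row_kronecker(Bu, Bv)
  p <- ncol(B)
  stop_if(p > n, "spline configuration needs ", p, " coefficients but only ",
          n, " measurements are available", class = "insufficient_data")

  A <- B; y <- f
  if (smoothing > 0) {
    P <- coef_penalty(ncol(Bu), ncol(Bv))
    A <- rbind(B, sqrt(smoothing) * P)
    y <- c(f, rep(0, nrow(P)))
  }
  qr_A <- qr(A)
  stop_if(qr_A$rank < p,
          "degenerate design: rank ", qr_A$rank, " < ", p,
          " coefficients (measurement shapes too collinear in (width, P/A))",
          class = "degenerate_design")
  beta <- qr.coef(qr_A, y)

  structure(list(
    key = key,
    degrees = degrees,
    smoothing = smoothing,
    n_knots = n_knots,
    knots_u = knots_u, knots_v = knots_v,
    width_range = wr, pa_range = rr,
    coef = t(matrix(beta, ncol(Bv), ncol(Bu))),  # beta has the P/A index fastest
    training = records[c("shape_id", "width_cm", "pa_ratio_per_cm", "insert_factor")]
  ), class = "insert_spline")
}

auto_knot_counts <- function(n, degrees) {
  kw <- 0L
  while ((degrees[1] + 2L + kw) * (degrees[2] + 1L) <= n - 2L && kw < 3L) {
    kw <- kw + 1L
  }
  c(kw, 0L)
}

clamped_knots <- function(x, degree, n_interior) {
  interior <- if (n_interior > 0) {
    as.numeric(quantile(x, probs = seq_len(n_interior) / (n_interior + 1),
                        names = FALSE))
  } else numeric(0)
  c(rep(0, degree + 1), interior, rep(1, degree + 1))
}

# B-spline basis with polynomial extension beyond [0, 1]: outside the knot
# span the boundary polynomial piece is continued via its Taylor expansion
# (exact, since the spline is piecewise polynomial). Extrapolation is the
# caller's risk and is flagged by predict_factor().
basis_matrix <- function(x, knots, degree) {
  ord <- degree + 1
  p <- length(knots) - ord
  out <- matrix(0, length(x), p)
  inside <- x >= 0 & x <= 1
  if (any(inside)) {
    out[inside, ] <- splines::splineDesign(knots, x[inside], ord = ord)
  }
  for (i in which(!inside)) {
    # Taylor expansion around the midpoint of the boundary polynomial
    # piece (one-sided derivative limits at the boundary knot itself are
    # unreliable)
    x0 <- if (x[i] < 0) {
      min(knots[knots > 0]) / 2
    } else {
      (max(knots[knots < 1]) + 1) / 2
    }
    D <- splines::splineDesign(knots, rep(x0, ord), ord = ord, derivs = 0:degree)
    dx <- x[i] - x0
    out[i, ] <- colSums(D * dx^(0:degree) / factorial(0:degree))
  }
  out
}

row_kronecker <- function(A, B) {
  out <- matrix(0, nrow(A), ncol(A) * ncol(B))
  for (i in seq_len(ncol(A))) {
    out[, (i - 1) * ncol(B) + seq_len(ncol(B))] <- A[, i] * B
  }
  out
}

# second-difference penalty on the coefficient grid along each axis;
# directions with fewer than 3 coefficients (e.g. the linear P/A axis)
# contribute no rows, so constants and planes are never penalized
coef_penalty <- function(pu, pv) {
  diff_mat <- function(p) {
    if (p >= 3) diff(diag(p), differences = 2) else matrix(0, 0, p)
  }
  rbind(kronecker(diff_mat(pu), diag(pv)),
        kronecker(diag(pu), diff_mat(pv)))
}

#' @export
print.insert_spline <- function(x, ...) {
  cat(sprintf(
    "<insert_spline: group %s, %d training shapes, degrees (%d, %d), smoothing %g>\n",
    x$key, nrow(x$training), x$degrees[1], x$degrees[2], x$smoothing))
  cat(sprintf("  width %.2f-%.2f cm, P/A %.3f-%.3f /cm\n",
              x$width_range[1], x$width_range[2],
              x$pa_range[1], x$pa_range[2]))
  invisible(x)
}

#' Predict the insert factor for a parameterized shape
#'
#' Evaluates a fitted spline at the query's (width, P/A) coordinates.
#' Queries outside the convex hull of the training points are still
#' evaluated (the boundary polynomial is continued) but flagged as
#' extrapolation with a warning: extrapolated factors must be reviewed
#' against a measurement before clinical use.
#'
#' @param model an [fit_insert_model()] result.
#' @param ellipse an [equivalent_ellipse()]; alternatively supply
#'   `width_cm` and `pa_ratio_per_cm` directly (vectorized).
#' @param width_cm,pa_ratio_per_cm query coordinates, used when `ellipse`
#'   is missing.
#' @return A list with `insert_factor` (numeric) and `extrapolated`
#'   (logical), each of query length.
#' @export
predict_factor <- function(model, ellipse = NULL, width_cm = NULL,
                           pa_ratio_per_cm = NULL) {
  stopifnot(inherits(model, "insert_spline"))
  if (!is.null(ellipse)) {
    width_cm <- ellipse$width_cm
    pa_ratio_per_cm <- ellipse$pa_ratio_per_cm
  }
  stop_if(is.null(width_cm) || is.null(pa_ratio_per_cm),
          "supply an equivalent ellipse or width/pa coordinates",
          class = "invalid_argument")
  u <- (width_cm - model$width_range[1]) / diff(model$width_range)
  v <- (pa_ratio_per_cm - model$pa_range[1]) / diff(model$pa_range)
  Bu <- basis_matrix(u, model$knots_u, model$degrees[1])
  Bv <- basis_matrix(v, model$knots_v, model$degrees[2])
  fac <- rowSums((Bu %*% model$coef) * Bv)
  tu <- (model$training$width_cm - model$width_range[1]) / diff(model$width_range)
  tv <- (model$training$pa_ratio_per_cm - model$pa_range[1]) / diff(model$pa_range)
  extra <- !vapply(seq_along(u), function(i) {
    in_convex_hull(tu, tv, u[i], v[i])
  }, TRUE)
  if (any(extra)) {
    warning(sprintf(
      "%d of %d queries lie outside the training hull of group %s (extrapolation)",
      sum(extra), length(extra), model$key))
  }
  list(insert_factor = as.numeric(fac), extrapolated = extra)
}

#' @export
predict.insert_spline <- function(object, newdata, ...) {
  if (inherits(newdata, "equivalent_ellipse")) {
    return(predict_factor(object, ellipse = newdata))
  }
  predict_factor(object, width_cm = newdata$width_cm,
                 pa_ratio_per_cm = newdata$pa_ratio_per_cm)
}

#' Leave-one-out prediction errors for a measurement group
#'
#' Refits the model once per record with that record held out and
#' predicts it, giving a per-shape uncertainty diagnostic for the group.
#' Requires at least nine records so every fold retains the eight-point
#' model floor.
#'
#' @inheritParams fit_insert_model
#' @return A data frame with `shape_id`, `measured`, `predicted`,
#'   `percent_difference` (100 x (predicted - measured) / measured) and an
#'   attribute `mean_abs_pct`.
#' @export
loo_errors <- function(records, degrees = c(3, 1), smoothing = 1e-3,
                       n_knots = NULL) {
  records <- as.data.frame(records)
  n <- nrow(records)
  stop_if(n < 9, "leave-one-out needs >= 9 records so folds keep the ",
          "eight-point floor (got ", n, ")", class = "insufficient_data")
  out <- lapply(seq_len(n), function(i) {
    m <- fit_insert_model(records[-i, , drop = FALSE], degrees = degrees,
                          smoothing = smoothing, n_knots = n_knots)
    ee <- if (is.null(records$pa_ratio_per_cm)) {
      equivalent_ellipse(records$width_cm[i], records$length_cm[i])
    } else {
      list(width_cm = records$width_cm[i],
           pa_ratio_per_cm = records$pa_ratio_per_cm[i])
    }
    p <- suppressWarnings(
      predict_factor(m, width_cm = ee$width_cm,
                     pa_ratio_per_cm = ee$pa_ratio_per_cm))
    data.frame(
      shape_id = if (!is.null(records$shape_id)) records$shape_id[i] else as.character(i),
      measured = records$insert_factor[i],
      predicted = p$insert_factor,
      extrapolated = p$extrapolated)
  })
  res <- do.call(rbind, out)
  res$percent_difference <- 100 * (res$predicted - res$measured) / res$measured
  attr(res, "mean_abs_pct") <- mean(abs(res$percent_difference))
  res
}

#' Save or load a fitted model as versioned JSON
#'
#' @param model an `insert_spline`.
#' @param path JSON file.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   `insert_spline` (round-trip exact to full double precision).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "insert_spline"))
  doc <- list(
    format = "insertfactor-spline", version = 1L,
    key = model$key, degrees = model$degrees, smoothing = model$smoothing,
    n_knots = model$n_knots,
    knots_u = model$knots_u, knots_v = model$knots_v,
    width_range = model$width_range, pa_range = model$pa_range,
    coef = as.numeric(model$coef), coef_dim = dim(model$coef),
    training = model$training)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  stop_if(!identical(doc$format, "insertfactor-spline"),
          "not an insertfactor spline model: ", path, class = "parse_error")
  structure(list(
    key = doc$key, degrees = doc$degrees, smoothing = doc$smoothing,
    n_knots = doc$n_knots, knots_u = doc$knots_u, knots_v = doc$knots_v,
    width_range = doc$width_range, pa_range = doc$pa_range,
    coef = matrix(doc$coef, doc$coef_dim[1], doc$coef_dim[2]),
    training = as.data.frame(doc$training)
  ), class = "insert_spline")
}
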