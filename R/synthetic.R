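#' Synthetic insert-factor surface
#'
#' A smooth ground-truth factor function over the (width, P/A) plane used
#' to test every stage of the pipeline without real measurements:
#' \deqn{f(w, r) = plateau - a e^{-w/w_0} - b (r - r_0)_+}
#' The exponential term emulates the output drop of narrow inserts
#' (loss of lateral scatter equilibrium) and the hinge term a mild
#' penalty for shapes with large perimeter relative to area (edge
#' scatter). With the default parameters (`plateau` 1.0, `a` 0.25, `w0`
#' 2.5 cm, `b` 0.05 cm, `r0` 0.6 /cm) the surface stays within (0.5, 1.1)
#' over the clinical domain width 2-20 cm, P/A 0.2-2.0 /cm, and orders
#' factors the way clinical tables do: small narrow inserts about
#' 0.86-0.95, large inserts about 1.00.
#'
#' Measurement noise is homoscedastic Gaussian on the factor
#' (`noise_sd`, default 0.002, the scale of chamber-measurement
#' repeatability); draws use R's Mersenne-Twister generator seeded from
#' `seed`, so sampling is fully deterministic.
#'
#' @param plateau,a,w0,b,r0 surface parameters (see above).
#' @param noise_sd measurement noise SD on the factor.
#' @param seed integer seed for the noise generator.
#' @return An object of class `synthetic_surface`.
#' @export
synthetic_surface <- function(plateau = 1.0, a = 0.25, w0 = 2.5, b = 0.05,
                              r0 = 0.6, noise_sd = 0.002, seed = 1L) {
  stop_if(!is_number(noise_sd) || noise_sd < 0, "noise_sd must be >= 0",
          class = "invalid_argument")
  structure(list(plateau = plateau, a = a, w0 = w0, b = b, r0 = r0,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_surface")
}

#' @rdname synthetic_surface
#' @param surface a `synthetic_surface`.
#' @param width_cm,pa_ratio_per_cm evaluation coordinates (vectorized).
#' @return `surface_factor` returns the noise-free factor.
#' @export
surface_factor <- function(surface, width_cm, pa_ratio_per_cm) {
  with(surface,
       plateau - a * exp(-width_cm / w0) -
         b * pmax(pa_ratio_per_cm - r0, 0))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  code
}

#' Sample synthetic measurements for a set of shapes
#'
#' Parameterizes each shape through the geometry pipeline and draws a
#' measured factor `f(width, P/A) + N(0, noise_sd)` from the surface's
#' seeded generator, producing records compatible with the measurement
#' database and model fit.
#'
#' @param surface a [synthetic_surface()].
#' @param shapes list of shapes as returned by
#'   [design_measurement_shapes()] (or a list of [polygon2d()]).
#' @param context a [beam_context()] stamped onto every record.
#' @return A data frame of measurement records (with `key` column).
#' @export
sample_measurements <- function(surface, shapes, context) {
  stopifnot(inherits(surface, "synthetic_surface"),
            inherits(context, "beam_context"))
  params <- shape_parameters(shapes)
  sample_from_parameters(surface, params, context)
}

shape_parameters <- function(shapes) {
  rows <- lapply(seq_along(shapes), function(i) {
    s <- shapes[[i]]
    poly <- if (inherits(s, "polygon2d")) s else s$polygon
    ee <- parameterize_shape(poly)
    data.frame(
      shape_id = if (!is.null(s$label)) s$label else sprintf("shape-%02d", i),
      width_cm = ee$width_cm, length_cm = ee$length_cm,
      pa_ratio_per_cm = ee$pa_ratio_per_cm)
  })
  do.call(rbind, rows)
}

sample_from_parameters <- function(surface, params, context) {
  f <- surface_factor(surface, params$width_cm, params$pa_ratio_per_cm)
  noise <- if (surface$noise_sd > 0) {
    with_seed(surface$seed, rnorm(nrow(params), 0, surface$noise_sd))
  } else rep(0, nrow(params))
  df <- data.frame(
    machine_id = context$machine_id,
    energy_mev = context$energy_mev,
    applicator_cm = context$applicator_cm,
    ssd_cm = context$ssd_cm,
    shape_id = params$shape_id,
    width_cm = params$width_cm,
    length_cm = params$length_cm,
    insert_factor = f + noise,
    pa_ratio_per_cm = params$pa_ratio_per_cm)
  df$key <- db_key(df)
  df
}

#' Boundary-only versus augmented design recovery experiment
#'
#' Quantifies how well the full pipeline (parameterize, sample, fit,
#' predict) recovers the ground-truth surface for one applicator, and
#' whether augmenting the eight bounding shapes with interior shapes
#' improves interior accuracy. For each replicate, noisy measurements of
#' a boundary-only design (`n_widths = 4`, no augmentation) and of an
#' augmented design (defaults of [design_measurement_shapes()]) are
#' fitted and both models are evaluated against the true surface at a
#' fixed set of probe shapes: a grid of ellipses realizable in the cone
#' whose (width, P/A) parameters fall inside the training hulls of both
#' designs, so every probe is an interpolation of a physically possible
#' insert. (A raw grid over the hull would also probe coordinates above
#' the circle limit P/A = 4/width, where no insert shape can ever produce
#' data.)
#'
#' @param surface a [synthetic_surface()]; its `seed` is ignored in favor
#'   of per-replicate seeds derived from `seed`.
#' @param applicator_cm applicator side, cm.
#' @param n_replicates number of paired noise replicates.
#' @param seed base seed; replicate `i` uses `seed + i`.
#' @param n_probes number of interior probe points.
#' @param ... further arguments (`degrees`, `smoothing`, `n_knots`) passed
#'   to [fit_insert_model()].
#' @return A list with `replicates` (per-replicate data frame: design,
#'   bias, rmse, max_abs) and `summary` (per-design means and the
#'   worst-replicate max error).
#' @export
recovery_experiment <- function(surface = synthetic_surface(),
                                applicator_cm = 10, n_replicates = 20,
                                seed = 42L, n_probes = 50, ...) {
  stop_if(n_replicates < 1, "n_replicates must be >= 1",
          class = "invalid_argument")
  ctx <- beam_context("synthetic", 12, applicator_cm, 100)
  boundary <- shape_parameters(
    design_measurement_shapes(applicator_cm, n_widths = 4, augment = FALSE))
  augmented <- shape_parameters(design_measurement_shapes(applicator_cm))
  probes <- probe_shape_parameters(applicator_cm, list(boundary, augmented),
                                   n_probes)
  truth <- surface_factor(surface, probes$width_cm, probes$pa_ratio_per_cm)

  one <- function(params, design, i) {
    s <- surface
    s$seed <- as.integer(seed + i)
    recs <- sample_from_parameters(s, params, ctx)
    m <- fit_insert_model(recs, ...)
    pred <- suppressWarnings(
      predict_factor(m, width_cm = probes$width_cm,
                     pa_ratio_per_cm = probes$pa_ratio_per_cm))$insert_factor
    err <- pred - truth
    data.frame(replicate = i, design = design, bias = mean(err),
               rmse = sqrt(mean(err^2)), max_abs = max(abs(err)))
  }
  reps <- do.call(rbind, lapply(seq_len(n_replicates), function(i) {
    rbind(one(boundary, "boundary", i), one(augmented, "augmented", i))
  }))
  summ <- do.call(rbind, lapply(split(reps, reps$design), function(g) {
    data.frame(design = g$design[1], mean_bias = mean(g$bias),
               mean_rmse = mean(g$rmse), mean_max_abs = mean(g$max_abs),
               worst_max_abs = max(g$max_abs))
  }))
  rownames(summ) <- NULL
  list(replicates = reps, summary = summ)
}

# deterministic probe set: (width, P/A) parameters of a grid of ellipses
# realizable in the cone, restricted to the convex hulls of all supplied
# training designs so every probe is an interpolation query
probe_shape_parameters <- function(applicator_cm, designs, n_probes) {
  L <- unname(APPLICATOR_MAX_LENGTH[as.character(applicator_cm)])
  if (is.na(L) || is.null(L)) L <- 1.3 * applicator_cm
  k <- ceiling(sqrt(n_probes * 2.5))
  g <- expand.grid(w = seq(2.6, applicator_cm - 0.6, length.out = k),
                   l = seq(2.6, L - 0.1, length.out = k))
  g <- g[g$l >= g$w, , drop = FALSE]
  ee <- lapply(seq_len(nrow(g)), function(i) equivalent_ellipse(g$w[i], g$l[i]))
  probes <- data.frame(
    width_cm = vapply(ee, `[[`, 0, "width_cm"),
    pa_ratio_per_cm = vapply(ee, `[[`, 0, "pa_ratio_per_cm"))
  inside <- rep(TRUE, nrow(probes))
  for (d in designs) {
    rw <- range(d$width_cm); rr <- range(d$pa_ratio_per_cm)
    u <- (d$width_cm - rw[1]) / diff(rw)
    v <- (d$pa_ratio_per_cm - rr[1]) / diff(rr)
    inside <- inside & vapply(seq_len(nrow(probes)), function(i) {
      in_convex_hull(u, v, (probes$width_cm[i] - rw[1]) / diff(rw),
                     (probes$pa_ratio_per_cm[i] - rr[1]) / diff(rr))
    }, TRUE)
  }
  probes <- probes[inside, , drop = FALSE]
  if (nrow(probes) > n_probes) {
    probes <- probes[round(seq(1, nrow(probes), length.out = n_probes)), ]
  }
  probes
}

#' Emit a synthetic measurement database
#'
#' Builds a database of synthetic measured insert factors for every
#' requested (energy, applicator, SSD) combination of one machine, using
#' the recommended measurement design per applicator, and writes it in
#' the measurement-database CSV format. The shipped surface is synthetic:
#' it emulates the qualitative structure of measured factor tables, not
#' any particular machine.
#'
#' @param surface a [synthetic_surface()].
#' @param path output CSV.
#' @param machine_id machine name stamped on the records.
#' @param energies_mev,applicators_cm,ssds_cm grids to cover.
#' @param seed base seed; each group uses an offset seed.
#' @return The loaded `measurement_db`, invisibly.
#' @export
simulate_database <- function(surface = synthetic_surface(), path,
                              machine_id = "synthetic",
                              energies_mev = c(6, 9, 12, 16, 20),
                              applicators_cm = c(6, 10, 15, 20),
                              ssds_cm = c(100, 105, 110),
                              seed = 1L) {
  combos <- expand.grid(energy = energies_mev, app = applicators_cm,
                        ssd = ssds_cm)
  param_cache <- lapply(setNames(nm = as.character(applicators_cm)),
                        function(a) {
                          shape_parameters(design_measurement_shapes(as.numeric(a)))
                        })
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    s <- surface
    s$seed <- as.integer(seed + i)
    ctx <- beam_context(machine_id, combos$energy[i], combos$app[i],
                        combos$ssd[i])
    sample_from_parameters(s, param_cache[[as.character(combos$app[i])]], ctx)
  })
  db <- do.call(rbind, rows)
  save_measurement_db(db, path)
  invisible(load_measurement_db(path))
}
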