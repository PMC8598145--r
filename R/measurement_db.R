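DB_COLUMNS <- c("machine_id", "energy_mev", "applicator_cm", "ssd_cm",
                "shape_id", "width_cm", "length_cm", "insert_factor",
                "dmax_cm", "polygon_file")

db_key <- function(df) {
  paste(df$machine_id, df$energy_mev, df$applicator_cm, df$ssd_cm, sep = "|")
}

#' Load a measurement database
#'
#' The database is a UTF-8 CSV with header and columns `machine_id,
#' energy_mev, applicator_cm, ssd_cm, shape_id, width_cm, length_cm,
#' insert_factor` plus optional `dmax_cm` and `polygon_file`. Each row is
#' one measured insert factor with the equivalent-ellipse parameters of
#' the shape it was measured with; rows are grouped by the
#' (machine, energy, applicator, SSD) key, and one spline model is fitted
#' per group. The perimeter-to-area ratio is derived deterministically
#' from width and length via [equivalent_ellipse()].
#'
#' When a row references a `polygon_file`, the polygon is re-parameterized
#' and a warning is raised if its width or length disagrees with the
#' stored values by more than 1%.
#'
#' @param path CSV file.
#' @param factor_bounds sanity bounds on the insert factor.
#' @param base_dir directory against which relative `polygon_file` paths
#'   are resolved (defaults to the database's directory).
#' @return A `measurement_db` object: a data frame of records with a
#'   derived `pa_ratio_per_cm` column and a `key` column.
#' @export
load_measurement_db <- function(path, factor_bounds = c(0.5, 1.2),
                                base_dir = dirname(path)) {
  stop_if(!file.exists(path), "database file not found: ", path,
          class = "io_error")
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) {
      stop(errorCondition(paste0("cannot parse ", path, ": ", conditionMessage(e)),
                          class = c("parse_error", "insertfactor_error")))
    })
  required <- setdiff(DB_COLUMNS, c("dmax_cm", "polygon_file"))
  missing <- setdiff(required, names(df))
  stop_if(length(missing) > 0, "missing database columns: ",
          paste(missing, collapse = ", "), class = "parse_error")
  num_cols <- c("energy_mev", "applicator_cm", "ssd_cm", "width_cm",
                "length_cm", "insert_factor")
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]))
    stop_if(length(bad) > 0, "non-numeric ", cl, " at data row ", bad[1],
            class = "parse_error")
    bad <- which(is.na(v))
    stop_if(length(bad) > 0, "missing ", cl, " at data row ", bad[1],
            class = "parse_error")
    df[[cl]] <- v
  }
  bad <- which(df$insert_factor <= factor_bounds[1] |
                 df$insert_factor >= factor_bounds[2])
  stop_if(length(bad) > 0, "insert_factor out of bounds (",
          factor_bounds[1], ", ", factor_bounds[2], ") at data row ", bad[1],
          class = "validation_error")
  bad <- which(df$width_cm > df$length_cm * (1 + 1e-9))
  stop_if(length(bad) > 0, "width_cm > length_cm at data row ", bad[1],
          class = "validation_error")
  key <- db_key(df)
  dup <- which(duplicated(paste(key, df$shape_id)))
  stop_if(length(dup) > 0, "duplicate (group, shape_id) at data row ", dup[1],
          class = "validation_error")
  df$pa_ratio_per_cm <- vapply(seq_len(nrow(df)), function(i) {
    equivalent_ellipse(df$width_cm[i], df$length_cm[i])$pa_ratio_per_cm
  }, 0)
  if (!is.null(df$polygon_file)) {
    for (i in which(nzchar(trimws(df$polygon_file %||% "")))) {
      pf <- df$polygon_file[i]
      if (!file.exists(pf)) pf <- file.path(base_dir, pf)
      ee <- parameterize_shape(read_polygon(pf))
      if (abs(ee$width_cm - df$width_cm[i]) > 0.01 * df$width_cm[i] ||
          abs(ee$length_cm - df$length_cm[i]) > 0.01 * df$length_cm[i]) {
        warning(sprintf(
          "row %d (%s): stored width/length (%.3f, %.3f) disagree with polygon (%.3f, %.3f) by >1%%",
          i, df$shape_id[i], df$width_cm[i], df$length_cm[i],
          ee$width_cm, ee$length_cm))
      }
    }
  }
  df$key <- key
  structure(df, class = c("measurement_db", "data.frame"))
}

#' Save a measurement database
#'
#' Numeric columns are written with 6 significant digits so that a
#' save/load cycle is bit-exact on the written text.
#'
#' @param db a `measurement_db` (or compatible data frame).
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
save_measurement_db <- function(db, path) {
  df <- as.data.frame(db)
  cols <- intersect(DB_COLUMNS, names(df))
  out <- df[cols]
  for (cl in names(out)) {
    if (is.numeric(out[[cl]])) out[[cl]] <- signif(out[[cl]], 6)
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Extract one model group from a database
#'
#' @param db a `measurement_db`.
#' @param machine_id,energy_mev,applicator_cm,ssd_cm group key, or pass a
#'   [beam_context()] as `machine_id`.
#' @return Data frame of the group's records.
#' @export
db_group <- function(db, machine_id, energy_mev = NULL, applicator_cm = NULL,
                     ssd_cm = NULL) {
  if (inherits(machine_id, "beam_context")) {
    ctx <- machine_id
    machine_id <- ctx$machine_id; energy_mev <- ctx$energy_mev
    applicator_cm <- ctx$applicator_cm; ssd_cm <- ctx$ssd_cm
  }
  key <- paste(machine_id, energy_mev, applicator_cm, ssd_cm, sep = "|")
  g <- as.data.frame(db)[db$key == key, , drop = FALSE]
  stop_if(nrow(g) == 0, "no measurements for group ", key,
          class = "missing_group")
  g
}

# practical maximum insert length per applicator (cm at the 100 cm plane);
# slightly below the geometric cone diagonal so the cut shape is machinable
APPLICATOR_MAX_LENGTH <- c(`6` = 7, `10` = 13, `15` = 19, `20` = 21)

#' Recommended measurement shapes for a model
#'
#' Builds the bounding-shape measurement design for one applicator: long
#' ellipses whose length is the (practical) maximum diagonal dimension of
#' the cone with `n_widths` widths spanning the clinical range, plus
#' circles (ellipses of equal width and length) spanning the same width
#' range. Bounding shapes delimit the reachable (width, P/A) space with
#' the minimum number of measurements; for the larger cones interior
#' shapes (a mid-size square and, for 15/20 cm cones, mid-space
#' rectangles) are added, which was found to improve accuracy for inserts
#' in the middle of the parameter space.
#'
#' @param applicator_cm applicator side, cm.
#' @param n_widths number of distinct widths per family (>= 4); default 4
#'   for the 6 cm cone (8 shapes, the minimum model size) and 5 otherwise.
#' @param augment add interior shapes (default for cones >= 10 cm).
#' @param max_length_cm maximum ellipse length; defaults to a per-cone
#'   lookup (7, 13, 19, 21 cm for the standard cones) and otherwise to
#'   about 1.3 times the cone side.
#' @param min_width_cm smallest clinically practical width (default 2.5).
#' @return A list of shapes, each a list with `label`, `kind` and
#'   `polygon`.
#' @examples
#' length(design_measurement_shapes(6))   # 8
#' length(design_measurement_shapes(10))  # 11
#' @export
design_measurement_shapes <- function(applicator_cm,
                                      n_widths = if (applicator_cm < 10) 4L else 5L,
                                      augment = applicator_cm >= 10,
                                      max_length_cm = NULL,
                                      min_width_cm = 2.5) {
  stop_if(!is_number(applicator_cm) || applicator_cm <= 0,
          "applicator side must be positive", class = "invalid_argument")
  stop_if(n_widths < 4, "n_widths must be >= 4", class = "invalid_argument")
  L <- max_length_cm %||%
    unname(APPLICATOR_MAX_LENGTH[as.character(applicator_cm)])
  if (is.na(L) || is.null(L)) L <- round(2 * min(1.3 * applicator_cm,
                                                 sqrt(2) * applicator_cm)) / 2
  shapes <- list()
  add <- function(label, kind, polygon) {
    shapes[[length(shapes) + 1]] <<- list(label = label, kind = kind,
                                          polygon = polygon)
  }
  # long ellipses: width varies, length pinned to the cone's practical max
  w_max_ell <- min(0.7 * applicator_cm, L - 0.5)
  for (w in round(seq(min_width_cm, w_max_ell, length.out = n_widths), 1)) {
    add(sprintf("%g x %g ellipse", w, L), "ellipse", ellipse_polygon(w, L))
  }
  # circles: equal width and length, spanning the same width range
  for (d in round(seq(min_width_cm, applicator_cm - 0.5,
                      length.out = n_widths), 1)) {
    add(sprintf("%g circle", d), "circle", circle_polygon(d))
  }
  if (augment) {
    s_mid <- round(0.4 * applicator_cm * 2) / 2
    add(sprintf("%g x %g square", s_mid, s_mid), "rectangle",
        rectangle_polygon(s_mid, s_mid))
    if (applicator_cm >= 15) {
      w1 <- round(0.55 * applicator_cm); l1 <- L - 1
      add(sprintf("%g x %g rectangle", w1, l1), "rectangle",
          rectangle_polygon(w1, l1))
      w2 <- round(0.25 * applicator_cm); l2 <- round(0.8 * L)
      add(sprintf("%g x %g rectangle", w2, l2), "rectangle",
          rectangle_polygon(w2, l2))
    }
  }
  shapes
}

#' Coverage diagnostics for a prediction query
#'
#' Model predictions are interpolations: they are trustworthy inside the
#' convex hull of the training points in the (width, P/A) plane and
#' increasingly uncertain away from measured shapes. This reports whether
#' a query lies inside that hull and its distance to the nearest training
#' point, with both axes scaled to unit range over the training group so
#' the two (differently-dimensioned) coordinates contribute comparably.
#'
#' @param group data frame of training records (one database group).
#' @param query an [equivalent_ellipse()] (or list with `width_cm` and
#'   `pa_ratio_per_cm`).
#' @return List with `in_hull` (logical), `nearest_distance` (normalized
#'   units) and `nearest_shape_id`.
#' @export
coverage_report <- function(group, query) {
  stop_if(nrow(group) == 0, "empty training group", class = "invalid_argument")
  w <- group$width_cm; r <- group$pa_ratio_per_cm
  rw <- range(w); rr <- range(r)
  sw <- if (diff(rw) > 0) diff(rw) else 1
  sr <- if (diff(rr) > 0) diff(rr) else 1
  u <- (w - rw[1]) / sw; v <- (r - rr[1]) / sr
  qu <- (query$width_cm - rw[1]) / sw
  qv <- (query$pa_ratio_per_cm - rr[1]) / sr
  d <- sqrt((u - qu)^2 + (v - qv)^2)
  i <- which.min(d)
  list(in_hull = in_convex_hull(u, v, qu, qv),
       nearest_distance = d[i],
       nearest_shape_id = if (!is.null(group$shape_id)) group$shape_id[i] else NA)
}

# point-in-convex-hull with boundary counted as inside (tolerance 1e-9)
in_convex_hull <- function(x, y, qx, qy, tol = 1e-9) {
  h <- chull(x, y)
  if (length(h) == 1) {
    return(abs(qx - x[h]) < tol && abs(qy - y[h]) < tol)
  }
  if (length(h) == 2) {
    # degenerate hull: a segment
    ax <- x[h[1]]; ay <- y[h[1]]; bx <- x[h[2]]; by <- y[h[2]]
    cr <- (bx - ax) * (qy - ay) - (by - ay) * (qx - ax)
    if (abs(cr) > tol) return(FALSE)
    t <- ((qx - ax) * (bx - ax) + (qy - ay) * (by - ay)) /
      ((bx - ax)^2 + (by - ay)^2)
    return(t >= -tol && t <= 1 + tol)
  }
  hx <- x[h]; hy <- y[h]  # chull returns clockwise order
  n <- length(h)
  nx <- c(hx[-1], hx[1]); ny <- c(hy[-1], hy[1])
  cr <- (nx - hx) * (qy - hy) - (ny - hy) * (qx - hx)
  all(cr <= tol) || all(cr >= -tol)
}
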