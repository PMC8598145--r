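#' Monitor units for a clinical electron field
#'
#' Computes
#' \deqn{MU = \frac{Dose\,(cGy)}{(1\,cGy/MU) \times PrescribedIsodoseLine
#'   \times ConeFactor \times InsertFactor}}
#' where the cone (applicator) factor is the ratio of open-cone output at
#' treatment SSD to the reference 15x15 cone output at 100 SSD, and the
#' insert factor is the ratio of insert output to open-cone output at the
#' same SSD. Both factors are taken as given: the cone factor is a
#' commissioning measurement and the insert factor typically comes from
#' [predict_factor()].
#'
#' @param dose_cgy prescribed dose, cGy.
#' @param insert_factor dimensionless insert (cutout) factor.
#' @param cone_factor dimensionless cone (applicator) factor.
#' @param prescribed_isodose_fraction fraction of maximum dose at which
#'   the prescription is normalized (e.g. 0.9 for the 90% line).
#' @param calibration_cgy_per_mu reference calibration output (1 cGy/MU
#'   by convention).
#' @return Monitor units (numeric).
#' @examples
#' compute_mu(200, insert_factor = 1, prescribed_isodose_fraction = 0.9)
#' @export
compute_mu <- function(dose_cgy, insert_factor, cone_factor = 1,
                       prescribed_isodose_fraction = 1,
                       calibration_cgy_per_mu = 1) {
  vals <- c(dose_cgy, insert_factor, cone_factor,
            prescribed_isodose_fraction, calibration_cgy_per_mu)
  stop_if(any(!is.finite(vals)) || any(vals <= 0),
          "all prescription inputs must be positive and finite",
          class = "invalid_argument")
  stop_if(prescribed_isodose_fraction > 1,
          "prescribed isodose fraction must be <= 1", class = "invalid_argument")
  dose_cgy / (calibration_cgy_per_mu * prescribed_isodose_fraction *
                cone_factor * insert_factor)
}

#' Interpolate an insert factor in SSD
#'
#' Insert factors modeled at the three clinical SSDs (typically 100, 105
#' and 110 cm) follow a quadratic trend in SSD; the unique second-order
#' polynomial through the three nodes is evaluated at the target SSD.
#' This interpolation is preliminary (flagged as such in reports) and
#' targets outside the node range are extrapolations, reported with a
#' warning.
#'
#' @param ssd_cm numeric length 3: the modeled SSDs (distinct).
#' @param factors numeric length 3: insert factors at those SSDs.
#' @param target_ssd_cm SSD at which to interpolate.
#' @return The interpolated insert factor; attribute `extrapolated` is
#'   `TRUE` when the target lies outside the node range.
#' @examples
#' interpolate_ssd(c(100, 105, 110), c(1.00, 0.96, 0.90), 107.5)  # 0.9325
#' @export
interpolate_ssd <- function(ssd_cm, factors, target_ssd_cm) {
  stop_if(length(ssd_cm) != 3 || length(factors) != 3,
          "exactly three (SSD, factor) nodes are required",
          class = "invalid_argument")
  stop_if(anyDuplicated(ssd_cm) > 0, "SSD nodes must be distinct",
          class = "invalid_argument")
  stop_if(!is_number(target_ssd_cm), "target SSD must be a number",
          class = "invalid_argument")
  # Lagrange form of the unique quadratic through the three nodes
  val <- 0
  for (i in 1:3) {
    others <- ssd_cm[-i]
    val <- val + factors[i] *
      prod(target_ssd_cm - others) / prod(ssd_cm[i] - others)
  }
  extrapolated <- target_ssd_cm < min(ssd_cm) || target_ssd_cm > max(ssd_cm)
  if (extrapolated) {
    warning(sprintf("target SSD %g cm outside modeled range [%g, %g]",
                    target_ssd_cm, min(ssd_cm), max(ssd_cm)))
  }
  structure(val, extrapolated = extrapolated)
}

#' Render a prediction report
#'
#' Writes a plain-text report of a prediction (and, optionally, a PDF twin
#' with the cutout outline and its equivalent ellipse overlaid). The
#' report carries six sections: beam parameters, insert shape, shape
#' parameterization, calculated insert factor, diagnostics (extrapolation
#' and hull coverage, with a visible warning banner when the query left
#' the training hull), and provenance (model key, database file and
#' hash). Factors are printed to 3 decimals and monitor units to 1
#' decimal, round-half-even; full precision is retained internally.
#'
#' @param ctx a [beam_context()].
#' @param poly the cutout [polygon2d()].
#' @param ellipse its [equivalent_ellipse()].
#' @param insert_factor the predicted factor.
#' @param diagnostics optional list: `extrapolated` (logical),
#'   `coverage` ([coverage_report()] output), `model_key`,
#'   `database_file`, `ssd_interpolated` (logical), `mu` (monitor units),
#'   `dose_cgy`.
#' @param path output path for the text report; the PDF twin replaces the
#'   extension with `.pdf`.
#' @param pdf also render the PDF (default `TRUE`).
#' @return The report text, invisibly (character vector of lines).
#' @export
build_report <- function(ctx, poly, ellipse, insert_factor,
                         diagnostics = list(), path, pdf = TRUE) {
  stopifnot(inherits(ctx, "beam_context"))
  poly <- as_polygon2d(poly)
  d <- diagnostics
  banner <- isTRUE(d$extrapolated)
  lines <- c(
    "ELECTRON INSERT FACTOR REPORT",
    strrep("=", 60),
    if (banner) c(
      "*** WARNING: QUERY OUTSIDE MEASURED PARAMETER SPACE ***",
      "*** prediction is an extrapolation - verify by measurement ***",
      strrep("=", 60)),
    "",
    "[1] Beam parameters",
    sprintf("    Machine:        %s", ctx$machine_id),
    sprintf("    Energy:         %g MeV", ctx$energy_mev),
    sprintf("    Applicator:     A%02d (%g cm)", round(ctx$applicator_cm),
            ctx$applicator_cm),
    sprintf("    SSD:            %g cm", ctx$ssd_cm),
    "",
    "[2] Insert shape",
    sprintf("    Vertices:       %d", length(poly$x)),
    sprintf("    Area:           %s cm^2", fmt_dec(polygon_area(poly), 3)),
    sprintf("    Perimeter:      %s cm", fmt_dec(polygon_perimeter(poly), 3)),
    sprintf("    Extent:         %s x %s cm",
            fmt_dec(diff(range(poly$x)), 2), fmt_dec(diff(range(poly$y)), 2)),
    "",
    "[3] Shape parameterization (equivalent ellipse)",
    sprintf("    Width:          %s cm", fmt_dec(ellipse$width_cm, 3)),
    sprintf("    Length:         %s cm", fmt_dec(ellipse$length_cm, 3)),
    sprintf("    Area:           %s cm^2", fmt_dec(ellipse$area_cm2, 3)),
    sprintf("    P/A ratio:      %s /cm", fmt_dec(ellipse$pa_ratio_per_cm, 4)),
    "",
    "[4] Calculated insert factor",
    sprintf("    Insert factor:  %s", fmt_dec(insert_factor, 3)),
    if (!is.null(d$mu)) sprintf("    MU (%s cGy):    %s",
                                format(d$dose_cgy %||% NA), fmt_dec(d$mu, 1)),
    if (isTRUE(d$ssd_interpolated))
      "    Note: SSD-interpolated factor (preliminary technique).",
    "",
    "[5] Diagnostics",
    sprintf("    Extrapolation:  %s", if (banner) "YES (outside training hull)" else "no"),
    if (!is.null(d$coverage)) c(
      sprintf("    In hull:        %s", d$coverage$in_hull),
      sprintf("    Nearest shape:  %s (distance %s, normalized)",
              d$coverage$nearest_shape_id, fmt_dec(d$coverage$nearest_distance, 3))),
    "",
    "[6] Provenance",
    sprintf("    Model key:      %s", d$model_key %||% "(unspecified)"),
    sprintf("    Database:       %s", d$database_file %||% "(unspecified)"),
    if (!is.null(d$database_file) && file.exists(d$database_file))
      sprintf("    Database hash:  %s", file_hash(d$database_file)),
    sprintf("    Generated:      %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("    Software:       insertfactor %s",
            as.character(utils::packageVersion("insertfactor")))
  )
  writeLines(lines, path)
  if (pdf) {
    pdf_path <- sub("\\.[[:alnum:]]+$", ".pdf", path)
    if (identical(pdf_path, path)) pdf_path <- paste0(path, ".pdf")
    render_report_pdf(lines, poly, ellipse, pdf_path)
  }
  invisible(lines)
}

render_report_pdf <- function(lines, poly, ellipse, pdf_path) {
  grDevices::pdf(pdf_path, width = 8.5, height = 11)
  on.exit(grDevices::dev.off())
  op <- par(mfrow = c(2, 1), mar = c(1, 1, 1, 1))
  on.exit(par(op), add = TRUE, after = FALSE)
  plot.new()
  n <- length(lines)
  text(0, seq(1, 0, length.out = n), lines, adj = c(0, 1),
       family = "mono", cex = 0.7)
  # outline with the equivalent ellipse overlaid (centered on the
  # inscribed-circle center for display)
  cen <- largest_inscribed_circle(poly)$center
  th <- seq(0, 2 * pi, length.out = 181)
  ex <- cen[1] + ellipse$width_cm / 2 * cos(th)
  ey <- cen[2] + ellipse$length_cm / 2 * sin(th)
  plot(c(poly$x, poly$x[1]), c(poly$y, poly$y[1]), type = "l", asp = 1,
       axes = FALSE, xlab = "", ylab = "", col = "black", lwd = 2)
  lines(ex, ey, col = "red", lty = 2)
  legend("topright", bty = "n", lty = c(1, 2), col = c("black", "red"),
         legend = c("insert outline", "equivalent ellipse"), cex = 0.8)
  invisible(pdf_path)
}

# order-independent content hash without extra dependencies: file size plus
# a simple polynomial rolling checksum of the bytes
file_hash <- function(path) {
  b <- as.integer(readBin(path, "raw", file.size(path)))
  h <- 0
  for (chunk in split(b, ceiling(seq_along(b) / 4096))) {
    h <- (h * 31 + sum(chunk * (seq_along(chunk) %% 97 + 1))) %% 2147483647
  }
  sprintf("%d-%010d", length(b), h)
}
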