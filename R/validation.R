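#' Load a validation-comparison table
#'
#' Reads a CSV of measured-versus-predicted insert factors. Required
#' columns: `label`, `energy_mev`, `applicator_cm`, `ssd_cm`,
#' `measured_factor`, `calculated_factor`, `percent_difference`; optional
#' `dmax_cm` and `dimensions`. The sign convention for the percent
#' difference is `100 * (calculated - measured) / measured`.
#'
#' Two fixture tables transcribed from a published validation of this
#' technique on clinical linear accelerators ship with the package:
#' `validation_fixture("patients")` (22 patient inserts) and
#' `validation_fixture("standard")` (26 standard inserts).
#'
#' @param path CSV file.
#' @return A data frame of validation pairs.
#' @export
load_validation_table <- function(path) {
  stop_if(!file.exists(path), "validation table not found: ", path,
          class = "io_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("label", "energy_mev", "applicator_cm", "ssd_cm",
                "measured_factor", "calculated_factor", "percent_difference")
  missing <- setdiff(required, names(df))
  stop_if(length(missing) > 0, "missing validation columns: ",
          paste(missing, collapse = ", "), class = "parse_error")
  df
}

#' @rdname load_validation_table
#' @param which `"patients"` or `"standard"`.
#' @export
validation_fixture <- function(which = c("patients", "standard")) {
  which <- match.arg(which)
  f <- system.file("extdata", sprintf("%s_inserts.csv", which),
                   package = "insertfactor", mustWork = TRUE)
  load_validation_table(f)
}

#' Summarize measured-versus-predicted agreement
#'
#' Aggregates the percent differences of a validation set. Percent
#' differences are taken from the table as given (published tables print
#' them alongside 3-decimal factors, and recomputing from the rounded
#' factors can shift a difference by up to 0.1 points); set
#' `recompute = TRUE` to derive them from the factor columns instead.
#'
#' Both the signed and the absolute-difference standard deviations are
#' reported and labeled: summaries in the field mix the two, and neither
#' bounds the other in general.
#'
#' @param pairs data frame from [load_validation_table()] (or with a
#'   `percent_difference` column).
#' @param recompute recompute differences from the factor columns.
#' @return A list of class `validation_summary`: `n`, `mean_abs_pct`,
#'   `max_abs_pct`, `mean_signed_pct`, `sd_signed_pct`, `sd_abs_pct`
#'   (both n-1).
#' @export
summarize_validation <- function(pairs, recompute = FALSE) {
  d <- if (recompute) {
    100 * (pairs$calculated_factor - pairs$measured_factor) / pairs$measured_factor
  } else {
    pairs$percent_difference
  }
  stop_if(is.null(d) || length(d) < 2,
          "need at least two validation pairs for dispersion statistics",
          class = "invalid_argument")
  stop_if(anyNA(d), "missing percent differences", class = "invalid_argument")
  structure(list(
    n = length(d),
    mean_abs_pct = mean(abs(d)),
    max_abs_pct = max(abs(d)),
    mean_signed_pct = mean(d),
    sd_signed_pct = sd(d),
    sd_abs_pct = sd(abs(d))
  ), class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf("<validation_summary: n = %d>\n", x$n))
  cat(sprintf("  mean |diff|   %s %%\n", fmt_dec(x$mean_abs_pct, 2)))
  cat(sprintf("  max  |diff|   %s %%\n", fmt_dec(x$max_abs_pct, 2)))
  cat(sprintf("  mean signed   %s %%\n", fmt_dec(x$mean_signed_pct, 2)))
  cat(sprintf("  SD signed     %s %% (n-1)\n", fmt_dec(x$sd_signed_pct, 2)))
  cat(sprintf("  SD |diff|     %s %% (n-1)\n", fmt_dec(x$sd_abs_pct, 2)))
  invisible(x)
}

#' Fit a Gaussian to a histogram of percent differences
#'
#' Bins the signed differences and least-squares fits a count-scaled
#' normal density `n * bin_width * dnorm(center, mu, sigma)` to the bin
#' counts, mirroring the histogram-plus-Gaussian summary customarily
#' reported for validation sets.
#'
#' @param differences signed percent differences (n >= 8).
#' @param bin_width histogram bin width in percent (default 0.5).
#' @return List with `mu`, `sigma` (percent), and the binned `histogram`
#'   data frame.
#' @export
fit_gaussian_histogram <- function(differences, bin_width = 0.5) {
  stop_if(length(differences) < 8, "need at least 8 differences",
          class = "invalid_argument")
  stop_if(!is_number(bin_width) || bin_width <= 0,
          "bin_width must be positive", class = "invalid_argument")
  lo <- floor(min(differences) / bin_width) * bin_width
  hi <- ceiling(max(differences) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (length(breaks) < 2) breaks <- c(lo, lo + bin_width)
  h <- graphics::hist(differences, breaks = breaks, plot = FALSE)
  centers <- h$mids; counts <- h$counts
  stop_if(sum(counts > 0) < 2,
          "degenerate histogram: all differences fall in one bin",
          class = "degenerate_fit")
  n <- length(differences)
  start <- list(mu = mean(differences), sigma = max(sd(differences), bin_width / 4))
  fit <- minpack.lm::nlsLM(
    counts ~ n * bin_width * stats::dnorm(centers, mu, sigma),
    start = start, data = data.frame(centers = centers, counts = counts),
    lower = c(mu = -Inf, sigma = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)
  list(mu = unname(est["mu"]), sigma = unname(est["sigma"]),
       histogram = data.frame(center = centers, count = counts))
}
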