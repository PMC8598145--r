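#' Beam context for an electron insert
#'
#' Bundles the machine, nominal energy, applicator (cone) and planned SSD
#' that together select the spline model used for a prediction.
#'
#' @param machine_id machine name, e.g. `"TrueBeam"`.
#' @param energy_mev nominal electron energy, MeV; must belong to
#'   `allowed_energies`.
#' @param applicator_cm applicator (cone) side length, cm; clinically 6,
#'   10, 15 or 20.
#' @param ssd_cm planned source-to-surface distance, cm.
#' @param allowed_energies permitted nominal energies, MeV.
#' @param ssd_bounds permitted SSD range, cm.
#' @return An object of class `beam_context`.
#' @export
beam_context <- function(machine_id, energy_mev, applicator_cm, ssd_cm,
                         allowed_energies = c(6, 9, 12, 16, 20),
                         ssd_bounds = c(100, 120)) {
  stop_if(!is.character(machine_id) || length(machine_id) != 1,
          "machine_id must be a single string", class = "invalid_context")
  stop_if(!is_number(energy_mev) || !(energy_mev %in% allowed_energies),
          "energy ", energy_mev, " MeV not in allowed set {",
          paste(allowed_energies, collapse = ", "), "}",
          class = "invalid_context")
  stop_if(!is_number(applicator_cm) || applicator_cm <= 0,
          "applicator side must be positive", class = "invalid_context")
  stop_if(!is_number(ssd_cm) || ssd_cm < ssd_bounds[1] || ssd_cm > ssd_bounds[2],
          "SSD ", ssd_cm, " cm outside bounds [", ssd_bounds[1], ", ",
          ssd_bounds[2], "]", class = "invalid_context")
  structure(list(machine_id = machine_id, energy_mev = energy_mev,
                 applicator_cm = applicator_cm, ssd_cm = ssd_cm),
            class = "beam_context")
}

#' @export
print.beam_context <- function(x, ...) {
  cat(sprintf("<beam_context: %s, %g MeV, A%02d, SSD %g cm>\n",
              x$machine_id, x$energy_mev, round(x$applicator_cm), x$ssd_cm))
  invisible(x)
}

RTPLAN_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.481.5"

#' Read an insert shape and beam context from a DICOM RT Plan
#'
#' Extracts the treatment machine, nominal electron energy, applicator and
#' planned SSD of one electron beam, together with its block (insert)
#' outline converted to cm in the beam's-eye-view plane at 100 cm. Block
#' coordinates are stored in mm; when the source-to-block-tray distance is
#' present they are rescaled from the tray plane to the 100 cm plane,
#' otherwise they are assumed to be at 100 cm already (see the package
#' vignette: this projection convention should be validated against an
#' export of the local planning system before clinical use).
#'
#' @param path RT Plan file.
#' @param beam_index 1-based beam selector, required when the plan holds
#'   more than one beam.
#' @param allowed_energies passed to [beam_context()]; non-integer nominal
#'   energies are rounded to the nearest allowed value with a warning.
#' @param applicator_map named numeric vector mapping applicator IDs to
#'   side lengths in cm; IDs of the form `"A10"`/`"A06"` are parsed
#'   directly when absent from the map.
#' @return A list with elements `context` ([beam_context()]) and `polygon`
#'   ([polygon2d()]).
#' @export
read_rtplan <- function(path, beam_index = NULL,
                        allowed_energies = c(6, 9, 12, 16, 20),
                        applicator_map = NULL) {
  ds <- dcm_read_file(path)
  beams <- dcm_get(ds, "300A,00B0")
  stop_if(is.null(beams) || length(beams) == 0, "RT Plan contains no beams",
          class = "no_insert")
  if (length(beams) > 1 && is.null(beam_index)) {
    stop(errorCondition(
      sprintf("plan contains %d beams; supply beam_index to select one",
              length(beams)),
      class = c("ambiguous_beam", "insertfactor_error")))
  }
  beam_index <- beam_index %||% 1L
  stop_if(beam_index < 1 || beam_index > length(beams),
          "beam_index out of range", class = "invalid_argument")
  beam <- beams[[beam_index]]

  rad_type <- dcm_get(beam, "300A,00C6", "")
  stop_if(!identical(toupper(rad_type), "ELECTRON"),
          "selected beam is not an electron beam (radiation type '",
          rad_type, "')", class = "wrong_modality")

  blocks <- dcm_get(beam, "300A,00F4")
  stop_if(is.null(blocks) || length(blocks) == 0,
          "electron beam carries no block/insert data", class = "no_insert")
  block <- blocks[[1]]
  xy_mm <- dcm_get(block, "300A,0106")
  stop_if(is.null(xy_mm) || length(xy_mm) < 6, "block data missing or too short",
          class = "no_insert")
  m <- matrix(xy_mm, ncol = 2, byrow = TRUE)
  tray_mm <- dcm_get(block, "300A,00F6")
  scale <- if (!is.null(tray_mm) && is.finite(tray_mm) && tray_mm > 0) {
    1000 / tray_mm  # tray plane -> 100 cm plane
  } else 1
  poly <- polygon2d(m[, 1] / 10 * scale, m[, 2] / 10 * scale)

  cps <- dcm_get(beam, "300A,0111")
  stop_if(is.null(cps) || length(cps) == 0, "beam has no control points",
          class = "dicom_error")
  energy <- dcm_get(cps[[1]], "300A,0114")
  stop_if(is.null(energy), "nominal beam energy missing", class = "dicom_error")
  if (!(energy %in% allowed_energies)) {
    nearest <- allowed_energies[which.min(abs(allowed_energies - energy))]
    warning(sprintf("nominal energy %g MeV not in allowed set; using %g MeV",
                    energy, nearest))
    energy <- nearest
  }
  ssd_mm <- dcm_get(cps[[1]], "300A,0130")
  stop_if(is.null(ssd_mm), "planned SSD missing", class = "dicom_error")

  apps <- dcm_get(beam, "300A,0107")
  stop_if(is.null(apps) || length(apps) == 0, "applicator data missing",
          class = "dicom_error")
  app_id <- dcm_get(apps[[1]], "300A,0108", "")
  applicator <- applicator_side_cm(app_id, applicator_map)

  ctx <- beam_context(
    machine_id = dcm_get(beam, "300A,00B2", "unknown"),
    energy_mev = energy,
    applicator_cm = applicator,
    ssd_cm = ssd_mm / 10,
    allowed_energies = allowed_energies)
  list(context = ctx, polygon = poly)
}

applicator_side_cm <- function(app_id, applicator_map = NULL) {
  if (!is.null(applicator_map) && app_id %in% names(applicator_map)) {
    return(unname(applicator_map[[app_id]]))
  }
  m <- regmatches(app_id, regexec("^A0*([0-9]+)", toupper(app_id)))[[1]]
  stop_if(length(m) < 2, "cannot interpret applicator ID '", app_id,
          "'; supply applicator_map", class = "dicom_error")
  as.numeric(m[2])
}

#' Write a minimal RT Plan fixture file
#'
#' Emits a standards-conformant explicit-VR little-endian RT Plan holding
#' one electron beam with an applicator, control point (energy, SSD) and
#' one block whose outline is the given polygon. `read_rtplan()` composed
#' with this writer is the identity on `(context, polygon)` up to float
#' rounding; the block outline is stored in mm at the block-tray plane.
#'
#' @param ctx a [beam_context()].
#' @param poly a [polygon2d()] in cm at the 100 cm plane.
#' @param path output file.
#' @param tray_distance_mm source-to-block-tray distance used to project
#'   the outline to the tray plane; `NA` stores the outline at the 100 cm
#'   plane with no tray tag.
#' @param radiation_type beam modality string (default `"ELECTRON"`;
#'   other values produce deliberately invalid fixtures for error-path
#'   testing).
#' @return `path`, invisibly.
#' @export
write_rtplan_fixture <- function(ctx, poly, path, tray_distance_mm = 950,
                                 radiation_type = "ELECTRON") {
  stopifnot(inherits(ctx, "beam_context"))
  poly <- as_polygon2d(poly)
  scale <- if (is.na(tray_distance_mm)) 1 else tray_distance_mm / 1000
  xy <- as.numeric(t(cbind(poly$x, poly$y))) * 10 * scale

  block <- list(
    dcm_el("300A,00F6", "DS", tray_distance_mm),
    dcm_el("300A,00FC", "IS", 1),
    dcm_el("300A,0104", "IS", length(poly$x)),
    dcm_el("300A,0106", "DS", xy))
  if (is.na(tray_distance_mm)) block <- block[-1]

  beam <- list(
    dcm_el("300A,00C0", "IS", 1),
    dcm_el("300A,00B2", "SH", ctx$machine_id),
    dcm_el("300A,00C6", "CS", radiation_type),
    dcm_el("300A,00F0", "IS", 1),
    dcm_el("300A,00F4", "SQ", list(block)),
    dcm_el("300A,0107", "SQ", list(list(
      dcm_el("300A,0108", "SH", sprintf("A%02d", round(ctx$applicator_cm))),
      dcm_el("300A,0109", "CS", "ELECTRON_SQUARE")))),
    dcm_el("300A,0111", "SQ", list(list(
      dcm_el("300A,0112", "IS", 0),
      dcm_el("300A,0114", "DS", ctx$energy_mev),
      dcm_el("300A,0130", "DS", ctx$ssd_cm * 10)))))

  sop_instance <- paste0("2.25.", paste(sample.int(9, 12, replace = TRUE) - 1,
                                        collapse = ""))
  dataset <- list(
    dcm_el("0008,0016", "UI", RTPLAN_SOP_CLASS),
    dcm_el("0008,0018", "UI", sop_instance),
    dcm_el("0008,0060", "CS", "RTPLAN"),
    dcm_el("300A,0002", "SH", "insert fixture"),
    dcm_el("300A,0070", "SQ", list(list(dcm_el("300A,0078", "IS", 1)))),
    dcm_el("300A,00B0", "SQ", list(beam)))
  dcm_write_file(path, dataset, RTPLAN_SOP_CLASS, sop_instance)
}
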