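# Minimal DICOM explicit-VR little-endian codec.
#
# Only the subset needed for RT Plan insert extraction is implemented:
# explicit VR, little endian, defined- or undefined-length sequences.
# Elements are lists (group, element, vr, value); SQ values are lists of
# items, each item a list of elements.

DCM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")
DCM_STR_VRS <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS",
                 "LO", "LT", "PN", "SH", "ST", "TM", "UI", "UT")
DCM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

dcm_el <- function(tag, vr, value) {
  g <- strtoi(substr(tag, 1, 4), 16L)
  e <- strtoi(substr(tag, 6, 9), 16L)
  list(group = g, element = e, vr = vr, value = value)
}

dcm_tag_chr <- function(group, element) sprintf("%04X,%04X", group, element)

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_encode_value <- function(vr, value) {
  if (vr == "SQ") {
    items <- lapply(value, function(item) {
      body <- dcm_encode_elements(item)
      c(u16(0xFFFE), u16(0xE000), u32(length(body)), body)
    })
    return(do.call(c, c(items, list(raw(0)))))
  }
  if (vr == "OB") {
    v <- as.raw(value)
    if (length(v) %% 2 == 1) v <- c(v, as.raw(0))
    return(v)
  }
  if (vr == "UL") return(u32(value))
  if (vr == "US") return(u16(value))
  if (vr == "FD") return(writeBin(as.numeric(value), raw(), size = 8, endian = "little"))
  if (vr == "FL") return(writeBin(as.numeric(value), raw(), size = 4, endian = "little"))
  if (vr %in% DCM_STR_VRS) {
    s <- if (vr %in% c("DS", "IS")) {
      paste(vapply(value, function(z) sprintf("%.10g", z), ""), collapse = "\\")
    } else paste(value, collapse = "\\")
    v <- charToRaw(s)
    if (length(v) %% 2 == 1) v <- c(v, if (vr == "UI") as.raw(0) else charToRaw(" "))
    return(v)
  }
  stop("unsupported VR for encoding: ", vr)
}

dcm_encode_element <- function(el) {
  body <- dcm_encode_value(el$vr, el$value)
  head <- c(u16(el$group), u16(el$element), charToRaw(el$vr))
  if (el$vr %in% DCM_LONG_VRS) {
    c(head, as.raw(c(0, 0)), u32(length(body)), body)
  } else {
    stopifnot(length(body) < 65536)
    c(head, u16(length(body)), body)
  }
}

dcm_encode_elements <- function(els) {
  do.call(c, c(lapply(els, dcm_encode_element), list(raw(0))))
}

# File meta (group 0002) + dataset, with 128-byte preamble and "DICM".
dcm_write_file <- function(path, dataset, sop_class, sop_instance) {
  meta <- list(
    dcm_el("0002,0001", "OB", as.raw(c(0, 1))),
    dcm_el("0002,0002", "UI", sop_class),
    dcm_el("0002,0003", "UI", sop_instance),
    dcm_el("0002,0010", "UI", DCM_EXPLICIT_LE),
    dcm_el("0002,0012", "UI", "2.25.437276171094384")
  )
  meta_body <- dcm_encode_elements(meta)
  out <- c(raw(128), charToRaw("DICM"),
           dcm_encode_element(dcm_el("0002,0000", "UL", length(meta_body))),
           meta_body,
           dcm_encode_elements(dataset))
  writeBin(out, path)
  invisible(path)
}

# --- reading ----------------------------------------------------------------

dcm_read_u16 <- function(raw, pos) {
  readBin(raw[pos:(pos + 1)], "integer", size = 2, endian = "little", signed = FALSE)
}
dcm_read_u32 <- function(raw, pos) {
  v <- readBin(raw[pos:(pos + 3)], "integer", size = 4, endian = "little")
  if (v < 0) NA_integer_ else v  # 0xFFFFFFFF -> undefined length
}

dcm_decode_value <- function(vr, body) {
  if (vr %in% c("DS", "IS")) {
    s <- trimws(rawToChar(body))
    if (!nzchar(s)) return(numeric(0))
    return(as.numeric(strsplit(s, "\\\\", fixed = FALSE)[[1]]))
  }
  if (vr %in% DCM_STR_VRS) {
    s <- rawToChar(body[body != as.raw(0)])
    return(sub("[ ]+$", "", s))
  }
  if (vr == "UL") return(dcm_read_u32(body, 1))
  if (vr == "US") return(dcm_read_u16(body, 1))
  if (vr == "FD") return(readBin(body, "double", n = length(body) / 8, size = 8, endian = "little"))
  if (vr == "FL") return(readBin(body, "double", n = length(body) / 4, size = 4, endian = "little"))
  body
}

# Parse elements in raw[pos..end]; returns list(elements, pos).
dcm_parse_elements <- function(raw, pos, end) {
  els <- list()
  while (pos <= end) {
    group <- dcm_read_u16(raw, pos)
    element <- dcm_read_u16(raw, pos + 2)
    if (group == 0xFFFE) break  # item/sequence delimiter: caller handles
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (vr %in% DCM_LONG_VRS) {
      len <- dcm_read_u32(raw, pos + 8)
      pos <- pos + 12
    } else {
      len <- dcm_read_u16(raw, pos + 6)
      pos <- pos + 8
    }
    if (vr == "SQ") {
      sq_end <- if (is.na(len)) end else pos + len - 1
      parsed <- dcm_parse_items(raw, pos, sq_end, undefined = is.na(len))
      value <- parsed$items
      pos <- parsed$pos
    } else {
      stop_if(is.na(len), "undefined length on non-SQ element",
              class = "dicom_error")
      value <- dcm_decode_value(vr, if (len > 0) raw[pos:(pos + len - 1)] else raw(0))
      pos <- pos + len
    }
    els[[dcm_tag_chr(group, element)]] <- list(group = group, element = element,
                                               vr = vr, value = value)
  }
  list(elements = els, pos = pos)
}

dcm_parse_items <- function(raw, pos, end, undefined) {
  items <- list()
  while (pos <= end) {
    group <- dcm_read_u16(raw, pos)
    element <- dcm_read_u16(raw, pos + 2)
    len <- dcm_read_u32(raw, pos + 4)
    pos <- pos + 8
    if (group == 0xFFFE && element == 0xE0DD) break  # sequence delimiter
    stop_if(group != 0xFFFE || element != 0xE000,
            "malformed sequence item", class = "dicom_error")
    if (is.na(len)) {
      parsed <- dcm_parse_elements(raw, pos, end)
      pos <- parsed$pos
      # expect item delimiter (FFFE,E00D)
      pos <- pos + 8
    } else {
      parsed <- dcm_parse_elements(raw, pos, pos + len - 1)
      pos <- pos + len
    }
    items[[length(items) + 1]] <- parsed$elements
  }
  list(items = items, pos = pos)
}

dcm_read_file <- function(path) {
  stop_if(!file.exists(path), "DICOM file not found: ", path, class = "io_error")
  raw <- readBin(path, "raw", file.size(path))
  stop_if(length(raw) < 140 || rawToChar(raw[129:132]) != "DICM",
          "not a DICOM part-10 file: ", path, class = "dicom_error")
  meta <- dcm_parse_elements(raw, 133, length(raw))
  # meta parser stops only at group change; re-scan: group 0002 elements first
  els <- meta$elements
  groups <- vapply(els, `[[`, 0, "group")
  meta_els <- els[groups == 2]
  ts <- meta_els[["0002,0010"]]$value %||% DCM_EXPLICIT_LE
  stop_if(!identical(ts, DCM_EXPLICIT_LE),
          "unsupported transfer syntax: ", ts, class = "dicom_error")
  els[groups != 2]
}

dcm_get <- function(els, tag, default = NULL) {
  v <- els[[tag]]
  if (is.null(v)) default else v$value
}
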