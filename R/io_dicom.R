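# Minimal DICOM RT Dose support.
#
# No DICOM package is available in the deployment stack, so a deliberately
# narrow reader is implemented here: single-frame RT Dose, explicit VR
# little endian only. Anything else is an explicit format error. A matching
# internal writer exists so the test suite can build fixtures at run time.

DCM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
RTDOSE_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.481.2"

dcm_u16 <- function(raw, off) readBin(raw[off + 1:2], "integer", size = 2,
                                      endian = "little", signed = FALSE)
dcm_u32 <- function(raw, off) {
  b <- as.numeric(as.integer(raw[off + 1:4]))
  b[1] + b[2] * 256 + b[3] * 65536 + b[4] * 16777216
}

# walk explicit-VR little-endian elements starting at byte offset `off`
# (0-based); returns list of (group, element, vr, value-raw)
dcm_walk <- function(raw, off, stop_after_group2 = FALSE) {
  n <- length(raw)
  out <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (off + 8 <= n) {
    group <- dcm_u16(raw, off)
    if (stop_after_group2 && group != 2L) break
    elem <- dcm_u16(raw, off + 2)
    vr <- rawToChar(raw[off + 5:6])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("DICOM: implicit VR or corrupt stream (explicit little endian required)")
    if (vr %in% long_vrs) {
      len <- dcm_u32(raw, off + 8)
      hdr <- 12L
    } else {
      len <- dcm_u16(raw, off + 6)
      hdr <- 8L
    }
    if (len == 4294967295)
      stop("DICOM: undefined element lengths are not supported")
    if (off + hdr + len > n) stop("DICOM: element overruns file")
    out[[length(out) + 1L]] <- list(group = group, elem = elem, vr = vr,
                                    value = raw[off + hdr + seq_len(len)])
    off <- off + hdr + len
  }
  list(elements = out, offset = off)
}

dcm_find <- function(elements, group, elem) {
  for (e in elements) if (e$group == group && e$elem == elem) return(e)
  NULL
}

dcm_str <- function(e) if (is.null(e)) NULL else
  sub("[ \\x00]+$", "", rawToChar(e$value))
dcm_ds <- function(e) if (is.null(e)) NULL else
  as.numeric(strsplit(dcm_str(e), "\\", fixed = TRUE)[[1]])
dcm_us <- function(e) if (is.null(e)) NULL else
  readBin(e$value, "integer", size = 2, endian = "little", signed = FALSE)

read_dicom_rt_dose <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("DICOM: missing DICM magic (not a DICOM part-10 file)")
  meta <- dcm_walk(raw, 132L, stop_after_group2 = TRUE)
  ts <- dcm_str(dcm_find(meta$elements, 0x0002, 0x0010))
  if (is.null(ts) || ts != DCM_EXPLICIT_LE)
    stop("DICOM: unsupported transfer syntax '", ts %||% "?",
         "' (explicit VR little endian required)")
  ds <- dcm_walk(raw, meta$offset)$elements

  nframes <- dcm_str(dcm_find(ds, 0x0028, 0x0008))
  if (!is.null(nframes) && as.integer(nframes) != 1L)
    stop("DICOM: multi-frame RT Dose not supported (single plane only)")
  rows <- dcm_us(dcm_find(ds, 0x0028, 0x0010))
  cols <- dcm_us(dcm_find(ds, 0x0028, 0x0011))
  spacing <- dcm_ds(dcm_find(ds, 0x0028, 0x0030))
  ipp <- dcm_ds(dcm_find(ds, 0x0020, 0x0032))
  scaling <- dcm_ds(dcm_find(ds, 0x3004, 0x000E))
  bits <- dcm_us(dcm_find(ds, 0x0028, 0x0100))
  pixrep <- dcm_us(dcm_find(ds, 0x0028, 0x0103))
  px <- dcm_find(ds, 0x7FE0, 0x0010)
  if (is.null(rows) || is.null(cols) || is.null(px))
    stop("DICOM: Rows/Columns/PixelData missing")
  if (is.null(spacing) || length(spacing) != 2L)
    stop("DICOM: Pixel Spacing missing; refusing to guess geometry")
  if (is.null(ipp) || length(ipp) < 2L)
    stop("DICOM: Image Position (Patient) missing; refusing to guess origin")
  if (is.null(scaling))
    stop("DICOM: Dose Grid Scaling missing")
  if (!is.null(pixrep) && pixrep != 0L)
    stop("DICOM: signed pixel data not supported")
  if (is.null(bits) || !(bits %in% c(16L, 32L)))
    stop("DICOM: Bits Allocated must be 16 or 32")

  if (bits == 16L) {
    ints <- readBin(px$value, "integer", n = rows * cols, size = 2,
                    endian = "little", signed = FALSE)
  } else {
    ints <- readBin(px$value, "integer", n = rows * cols, size = 4,
                    endian = "little")
    if (any(ints < 0)) stop("DICOM: 32-bit pixel values exceed signed range")
  }
  if (length(ints) != rows * cols) stop("DICOM: pixel data truncated")
  vals <- matrix(ints * scaling, nrow = rows, ncol = cols, byrow = TRUE)
  # Image Position (Patient) is (x, y, z) of the first pixel centre;
  # internal origin convention is (y, x)
  dose_plane(vals, spacing = spacing, origin = c(ipp[2], ipp[1]),
             quantity = "dose")
}

# --- internal writer (fixture construction; not part of the public API) ---

dcm_pad <- function(s, pad = as.raw(0L)) {
  b <- charToRaw(s)
  if (length(b) %% 2 == 1) b <- c(b, pad)
  b
}

dcm_elem <- function(group, elem, vr, value_raw) {
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  tag <- writeBin(as.integer(c(group, elem)), raw(), size = 2,
                  endian = "little")
  if (vr %in% long_vrs) {
    c(tag, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(as.integer(length(value_raw)), raw(), size = 4,
               endian = "little"), value_raw)
  } else {
    c(tag, charToRaw(vr),
      writeBin(as.integer(length(value_raw)), raw(), size = 2,
               endian = "little"), value_raw)
  }
}

dcm_elem_str <- function(group, elem, vr, s)
  dcm_elem(group, elem, vr, dcm_pad(s, if (vr == "UI") as.raw(0L) else charToRaw(" ")))
dcm_elem_us <- function(group, elem, v)
  dcm_elem(group, elem, "US", writeBin(as.integer(v), raw(), size = 2,
                                       endian = "little"))

write_dicom_rt_dose <- function(plane, path) {
  stopifnot(is_dose_plane(plane))
  maxv <- max(plane$values)
  scaling <- if (maxv > 0) maxv / 65535 else 1
  ints <- as.integer(round(plane$values / scaling))
  pixel <- writeBin(as.integer(t(ints)), raw(), size = 2, endian = "little")
  ds <- c(
    dcm_elem_str(0x0008, 0x0016, "UI", RTDOSE_SOP_CLASS),
    dcm_elem_str(0x0008, 0x0018, "UI", "1.2.826.0.1.3680043.9999.1"),
    dcm_elem_str(0x0020, 0x0032, "DS",
                 paste(formatC(c(plane$origin[2], plane$origin[1], 0),
                               format = "g", digits = 10), collapse = "\\")),
    dcm_elem_us(0x0028, 0x0002, 1L),
    dcm_elem_str(0x0028, 0x0008, "IS", "1"),
    dcm_elem_us(0x0028, 0x0010, nrow(plane$values)),
    dcm_elem_us(0x0028, 0x0011, ncol(plane$values)),
    dcm_elem_str(0x0028, 0x0030, "DS",
                 paste(formatC(plane$spacing, format = "g", digits = 10),
                       collapse = "\\")),
    dcm_elem_us(0x0028, 0x0100, 16L),
    dcm_elem_us(0x0028, 0x0101, 16L),
    dcm_elem_us(0x0028, 0x0102, 15L),
    dcm_elem_us(0x0028, 0x0103, 0L),
    dcm_elem_str(0x3004, 0x0002, "CS", "GY"),
    dcm_elem_str(0x3004, 0x000E, "DS",
                 formatC(scaling, format = "g", digits = 16)),
    dcm_elem(0x7FE0, 0x0010, "OW", pixel))
  meta_body <- c(
    dcm_elem(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_elem_str(0x0002, 0x0002, "UI", RTDOSE_SOP_CLASS),
    dcm_elem_str(0x0002, 0x0003, "UI", "1.2.826.0.1.3680043.9999.1"),
    dcm_elem_str(0x0002, 0x0010, "UI", DCM_EXPLICIT_LE))
  meta <- c(dcm_elem(0x0002, 0x0000, "UL",
                     writeBin(as.integer(length(meta_body)), raw(), size = 4,
                              endian = "little")),
            meta_body)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, ds), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
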