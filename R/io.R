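#' Read a 2D plane from file
#'
#' Supported formats:
#' \describe{
#'   \item{`csv-grid`}{the package's plain-text dialect: two header lines,
#'     `spacing_mm,<row>,<col>,<quantity>` and `origin_mm,<row>,<col>`,
#'     followed by comma-separated rows of values. Round-trips bit-exactly
#'     through [write_plane()].}
#'   \item{`dicom-rt-dose`}{single-frame DICOM RT Dose, explicit VR little
#'     endian. Pixel values are scaled by Dose Grid Scaling; the Grid Frame
#'     Offset Vector is ignored (single plane).}
#'   \item{`tiff-16bit`}{baseline uncompressed TIFF, 16 bits per channel RGB
#'     (film scans). Returns a list of three `dose_plane`s, one per channel,
#'     with spacing derived from the stored resolution (25.4/dpi mm).}
#' }
#' Missing geometry metadata is an error, never a silent default.
#'
#' @param path file path.
#' @param format one of `"csv-grid"`, `"dicom-rt-dose"`, `"tiff-16bit"`.
#' @return a [dose_plane], or for `tiff-16bit` a named list
#'   `list(R =, G =, B =)` of planes (quantity `"reading"`).
#' @export
read_plane <- function(path, format = c("csv-grid", "dicom-rt-dose", "tiff-16bit")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         "csv-grid" = read_csv_grid(path),
         "dicom-rt-dose" = read_dicom_rt_dose(path),
         "tiff-16bit" = read_tiff_rgb16(path))
}

#' Write a plane to the csv-grid format
#'
#' @param plane a [dose_plane].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plane <- function(plane, path) {
  stopifnot(is_dose_plane(plane))
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) formatC(x, format = "g", digits = 17)
  writeLines(c(
    paste(c("spacing_mm", num(plane$spacing), plane$quantity), collapse = ","),
    paste(c("origin_mm", num(plane$origin)), collapse = ",")), con)
  utils::write.table(matrix(num(plane$values), nrow(plane$values)), con,
                     sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

read_csv_grid <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4L) stop("csv-grid: file too short")
  h1 <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  h2 <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  if (h1[1] != "spacing_mm" || h2[1] != "origin_mm")
    stop("csv-grid: missing spacing_mm/origin_mm header lines")
  spacing <- as.numeric(h1[2:3])
  quantity <- if (length(h1) >= 4L) h1[4] else "dose"
  origin <- as.numeric(h2[2:3])
  if (any(is.na(spacing)) || any(is.na(origin)))
    stop("csv-grid: unparseable spacing/origin metadata")
  vals <- do.call(rbind, lapply(lines[-(1:2)], function(l)
    as.numeric(strsplit(l, ",", fixed = TRUE)[[1]])))
  if (any(is.na(vals))) stop("csv-grid: non-numeric grid values")
  dose_plane(vals, spacing, origin, quantity = quantity)
}
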