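# Minimal baseline TIFF support for film scans: little-endian, uncompressed,
# 16 bits per channel RGB, chunky layout. Mirrors the scan settings used for
# radiochromic film work (48-bit RGB transmission scans); everything else is
# rejected loudly. The writer backs the synthetic film-scan generator and the
# test fixtures; the reader is cross-validated against Python tifffile in the
# test suite.

tif_u16 <- function(raw, off) readBin(raw[off + 1:2], "integer", size = 2,
                                      endian = "little", signed = FALSE)
tif_u32 <- function(raw, off) {
  b <- as.numeric(as.integer(raw[off + 1:4]))
  b[1] + b[2] * 256 + b[3] * 65536 + b[4] * 16777216
}

tif_entry_values <- function(raw, entry_off) {
  tag <- tif_u16(raw, entry_off)
  type <- tif_u16(raw, entry_off + 2)
  count <- tif_u32(raw, entry_off + 4)
  size <- c(`1` = 1, `3` = 2, `4` = 4, `5` = 8)[as.character(type)]
  if (is.na(size)) return(list(tag = tag, values = NULL))
  total <- size * count
  off <- if (total <= 4) entry_off + 8 else tif_u32(raw, entry_off + 8)
  vals <- switch(as.character(type),
    `1` = as.numeric(as.integer(raw[off + seq_len(count)])),
    `3` = vapply(seq_len(count) - 1L, function(k) tif_u16(raw, off + 2 * k), 0),
    `4` = vapply(seq_len(count) - 1L, function(k) tif_u32(raw, off + 4 * k), 0),
    `5` = vapply(seq_len(count) - 1L, function(k) {
      tif_u32(raw, off + 8 * k) / tif_u32(raw, off + 8 * k + 4)
    }, 0))
  list(tag = tag, values = vals)
}

read_tiff_rgb16 <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8 || rawToChar(raw[1:2]) != "II" || tif_u16(raw, 2) != 42L)
    stop("TIFF: not a little-endian TIFF file")
  ifd <- tif_u32(raw, 4)
  nent <- tif_u16(raw, ifd)
  tags <- list()
  for (k in seq_len(nent) - 1L) {
    e <- tif_entry_values(raw, ifd + 2 + 12 * k)
    tags[[as.character(e$tag)]] <- e$values
  }
  g <- function(tag) tags[[as.character(tag)]]
  width <- g(256); height <- g(257)
  if (is.null(width) || is.null(height)) stop("TIFF: missing image dimensions")
  if (!is.null(g(259)) && g(259) != 1) stop("TIFF: compressed data not supported")
  bps <- g(258)
  spp <- g(277) %||% 1
  if (spp != 3 || length(bps) != 3 || any(bps != 16))
    stop("TIFF: expected 16-bit-per-channel RGB (48-bit) data")
  if (!is.null(g(284)) && g(284) != 1) stop("TIFF: planar layout not supported")
  xres <- g(282); yres <- g(283); unit <- g(296) %||% 2
  if (is.null(xres) || is.null(yres))
    stop("TIFF: missing resolution metadata; refusing to guess pixel spacing")
  if (unit != 2) stop("TIFF: only inch resolution units supported")
  spacing <- c(25.4 / yres, 25.4 / xres)  # (row, col) mm

  offsets <- g(273); counts <- g(279)
  if (is.null(offsets) || is.null(counts)) stop("TIFF: missing strip layout")
  data <- do.call(c, lapply(seq_along(offsets), function(i)
    raw[offsets[i] + seq_len(counts[i])]))
  npx <- width * height
  ints <- readBin(data, "integer", n = 3 * npx, size = 2, endian = "little",
                  signed = FALSE)
  if (length(ints) != 3 * npx) stop("TIFF: pixel data truncated")
  chan <- function(k) matrix(ints[seq(k, length(ints), by = 3)],
                             nrow = height, ncol = width, byrow = TRUE)
  mk <- function(m) dose_plane(m, spacing = spacing, quantity = "reading")
  list(R = mk(chan(1)), G = mk(chan(2)), B = mk(chan(3)))
}

# channels: named list R/G/B of integer-valued matrices in [0, 65535]
write_tiff_rgb16 <- function(channels, path, dpi = 75) {
  stopifnot(all(c("R", "G", "B") %in% names(channels)))
  R <- channels$R; G <- channels$G; B <- channels$B
  stopifnot(all(dim(R) == dim(G)), all(dim(R) == dim(B)))
  h <- nrow(R); w <- ncol(R)
  clip <- function(m) pmin(pmax(round(m), 0), 65535)
  inter <- matrix(0L, nrow = 3 * w, ncol = h)
  inter[seq(1, 3 * w, 3), ] <- t(clip(R))
  inter[seq(2, 3 * w, 3), ] <- t(clip(G))
  inter[seq(3, 3 * w, 3), ] <- t(clip(B))
  pixel <- writeBin(as.integer(inter), raw(), size = 2, endian = "little")

  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  entry <- function(tag, type, count, value_raw) {
    v <- value_raw
    if (length(v) < 4) v <- c(v, raw(4 - length(v)))
    c(u16(tag), u16(type), u32(count), v)
  }
  n_entries <- 12L
  ifd_off <- 8L
  after_ifd <- ifd_off + 2L + 12L * n_entries + 4L
  bps_off <- after_ifd          # 3 x SHORT = 6 bytes
  xres_off <- bps_off + 6L      # RATIONAL = 8 bytes
  yres_off <- xres_off + 8L
  strip_off <- yres_off + 8L
  entries <- c(
    entry(256, 4, 1, u32(w)),
    entry(257, 4, 1, u32(h)),
    entry(258, 3, 3, u32(bps_off)),
    entry(259, 3, 1, u16(1)),
    entry(262, 3, 1, u16(2)),
    entry(273, 4, 1, u32(strip_off)),
    entry(277, 3, 1, u16(3)),
    entry(278, 4, 1, u32(h)),
    entry(279, 4, 1, u32(length(pixel))),
    entry(282, 5, 1, u32(xres_off)),
    entry(283, 5, 1, u32(yres_off)),
    entry(296, 3, 1, u16(2)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), u16(42), u32(ifd_off),
             u16(n_entries), entries, u32(0),
             u16(c(16, 16, 16)),
             u32(c(dpi, 1)), u32(c(dpi, 1)),
             pixel), con)
  invisible(path)
}
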