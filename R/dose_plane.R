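#' 2D dose/reading plane
#'
#' The common currency of the package: a 2D scalar grid (planned dose, film
#' or EPID-like detector reading, optical density, or a gamma map) with a
#' physical geometry attached. Rows run along the in-plane (y) axis, columns
#' along the cross-plane (x) axis; the physical coordinate of pixel
#' \code{(i, j)} is \code{origin + ((i-1)*spacing[1], (j-1)*spacing[2])} mm,
#' addressed at pixel centres.
#'
#' @param values numeric matrix, at least 2 x 2, all values finite and
#'   non-negative (gamma maps and optical density included).
#' @param spacing length-2 numeric, (row, col) pixel pitch in mm; both > 0.
#'   A single number is recycled.
#' @param origin length-2 numeric, physical (y, x) coordinate in mm of the
#'   first sample \code{values[1, 1]}. Default places the grid centre at
#'   (0, 0).
#' @param quantity one of \code{"dose"}, \code{"reading"}, \code{"od"},
#'   \code{"gamma"}.
#' @return An object of class \code{dose_plane}: a list with elements
#'   \code{values}, \code{spacing}, \code{origin}, \code{quantity}.
#' @examples
#' p <- dose_plane(matrix(1, 5, 5), spacing = 2)
#' plane_axes(p)$x
#' @export
dose_plane <- function(values, spacing, origin = NULL,
                       quantity = c("dose", "reading", "od", "gamma")) {
  quantity <- match.arg(quantity)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("plane must be at least 2 x 2")
  if (!all(is.finite(values)))
    stop("plane values must all be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be two positive finite numbers (mm)")
  if (is.null(origin)) {
    origin <- c(-(nrow(values) - 1) / 2 * spacing[1],
                -(ncol(values) - 1) / 2 * spacing[2])
  }
  origin <- as.numeric(origin)
  if (length(origin) != 2L || any(!is.finite(origin)))
    stop("`origin` must be two finite numbers (mm)")
  structure(list(values = values, spacing = spacing, origin = origin,
                 quantity = quantity),
            class = "dose_plane")
}

#' @export
print.dose_plane <- function(x, ...) {
  cat(sprintf("<dose_plane> %d x %d [%s], spacing (%.4g, %.4g) mm, origin (%.4g, %.4g) mm\n",
              nrow(x$values), ncol(x$values), x$quantity,
              x$spacing[1], x$spacing[2], x$origin[1], x$origin[2]))
  cat(sprintf("  range [%.6g, %.6g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.dose_plane <- function(x) dim(x$values)

is_dose_plane <- function(x) inherits(x, "dose_plane")

#' Physical pixel-centre coordinates of a plane
#'
#' @param plane a [dose_plane].
#' @return list with numeric vectors \code{y} (row centres, mm) and
#'   \code{x} (column centres, mm).
#' @export
plane_axes <- function(plane) {
  stopifnot(is_dose_plane(plane))
  list(y = plane$origin[1] + (seq_len(nrow(plane$values)) - 1) * plane$spacing[1],
       x = plane$origin[2] + (seq_len(ncol(plane$values)) - 1) * plane$spacing[2])
}

same_geometry <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' 1D profile through a plane
#'
#' @param positions strictly increasing physical coordinates (mm).
#' @param values numeric vector, same length as `positions`.
#' @param axis `"cross-plane"` (along x) or `"in-plane"` (along y).
#' @return Object of class `qa_profile`.
#' @export
qa_profile <- function(positions, values, axis = c("cross-plane", "in-plane")) {
  axis <- match.arg(axis)
  positions <- as.numeric(positions); values <- as.numeric(values)
  if (length(positions) != length(values))
    stop("positions and values must have equal length")
  if (length(positions) < 2L || any(diff(positions) <= 0))
    stop("positions must be strictly increasing, length >= 2")
  if (!all(is.finite(positions)) || !all(is.finite(values)))
    stop("profile must be finite")
  structure(list(positions = positions, values = values, axis = axis),
            class = "qa_profile")
}

#' @export
print.qa_profile <- function(x, ...) {
  cat(sprintf("<qa_profile> %s, %d samples over [%.4g, %.4g] mm\n",
              x$axis, length(x$positions), min(x$positions), max(x$positions)))
  invisible(x)
}

#' Rectangular region of interest in physical mm
#'
#' Half-open on the max edges: a pixel belongs to the ROI iff its centre
#' satisfies `x_min <= x < x_max` and `y_min <= y < y_max`.
#'
#' @param x_min,x_max,y_min,y_max rectangle bounds in mm.
#' @return Object of class `qa_roi`.
#' @export
qa_roi <- function(x_min, x_max, y_min, y_max) {
  if (!(x_min < x_max) || !(y_min < y_max))
    stop("ROI requires x_min < x_max and y_min < y_max")
  structure(list(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max),
            class = "qa_roi")
}

roi_pixel_index <- function(plane, roi) {
  ax <- plane_axes(plane)
  list(rows = which(ax$y >= roi$y_min & ax$y < roi$y_max),
       cols = which(ax$x >= roi$x_min & ax$x < roi$x_max))
}

#' Mean, SD and count of pixels inside an ROI
#'
#' Sample SD (n - 1 denominator) throughout, matching the convention under
#' which the TG-119 confidence limits in this package reproduce their
#' reference values.
#'
#' @param plane a [dose_plane].
#' @param roi a [qa_roi]; pixel centres are tested against the half-open
#'   rectangle.
#' @return list with `mean`, `sd`, `n`. `sd` is `NA` when `n < 2`.
#' @export
roi_stats <- function(plane, roi) {
  stopifnot(is_dose_plane(plane), inherits(roi, "qa_roi"))
  idx <- roi_pixel_index(plane, roi)
  if (length(idx$rows) == 0L || length(idx$cols) == 0L)
    stop("ROI contains no pixel centres")
  v <- plane$values[idx$rows, idx$cols]
  n <- length(v)
  list(mean = mean(v), sd = if (n >= 2L) stats::sd(v) else NA_real_, n = n)
}

#' Extract a 1D profile from a plane
#'
#' A cross-plane profile runs along x at fixed y = `position`; an in-plane
#' profile runs along y at fixed x. Values are averaged over the band
#' `position +/- averaging_width/2` (pixel centres inside the closed band).
#'
#' @param plane a [dose_plane].
#' @param axis `"cross-plane"` or `"in-plane"`.
#' @param position band centre in mm along the perpendicular axis.
#' @param averaging_width band width in mm; 0 selects the single nearest
#'   line of pixels.
#' @return a [qa_profile].
#' @export
extract_profile <- function(plane, axis = c("cross-plane", "in-plane"),
                            position = 0, averaging_width = 0) {
  axis <- match.arg(axis)
  stopifnot(is_dose_plane(plane), averaging_width >= 0)
  ax <- plane_axes(plane)
  perp <- if (axis == "cross-plane") ax$y else ax$x
  half <- averaging_width / 2
  if (position - half < min(perp) - 1e-9 || position + half > max(perp) + 1e-9)
    stop("profile band lies (partly) outside the plane")
  sel <- which(perp >= position - half - 1e-9 & perp <= position + half + 1e-9)
  if (length(sel) == 0L) sel <- which.min(abs(perp - position))
  if (axis == "cross-plane") {
    vals <- colMeans(plane$values[sel, , drop = FALSE])
    qa_profile(ax$x, vals, axis = "cross-plane")
  } else {
    vals <- rowMeans(plane$values[, sel, drop = FALSE])
    qa_profile(ax$y, vals, axis = "in-plane")
  }
}

#' Bilinear interpolation of a plane at arbitrary physical points
#'
#' Points outside the grid return `NA`.
#'
#' @param plane a [dose_plane].
#' @param y,x numeric vectors of physical coordinates (mm), same length.
#' @return numeric vector of interpolated values.
#' @keywords internal
plane_interp <- function(plane, y, x) {
  v <- plane$values
  fi <- (y - plane$origin[1]) / plane$spacing[1]
  fj <- (x - plane$origin[2]) / plane$spacing[2]
  nr <- nrow(v); nc <- ncol(v)
  out <- rep(NA_real_, length(fi))
  ok <- fi >= 0 & fi <= nr - 1 & fj >= 0 & fj <= nc - 1
  if (!any(ok)) return(out)
  fi <- fi[ok]; fj <- fj[ok]
  i0 <- pmin(floor(fi), nr - 2); j0 <- pmin(floor(fj), nc - 2)
  di <- fi - i0; dj <- fj - j0
  i0 <- i0 + 1; j0 <- j0 + 1   # 1-based corners
  out[ok] <- v[cbind(i0, j0)] * (1 - di) * (1 - dj) +
    v[cbind(i0 + 1, j0)] * di * (1 - dj) +
    v[cbind(i0, j0 + 1)] * (1 - di) * dj +
    v[cbind(i0 + 1, j0 + 1)] * di * dj
  out
}

#' Round half away from zero
#'
#' The rounding convention of printed QA tables (base `round()` is
#' round-half-even); used whenever package output is compared against a
#' reference table at its printed precision.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
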