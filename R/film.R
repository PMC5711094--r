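# Radiochromic film dosimetry: optical density, per-channel cubic
# calibration (dose as a function of OD), dose mapping, and film-to-plan
# registration by normalized cross-correlation.

#' Cubic calibration curve: dose = c0 + c1*OD + c2*OD^2 + c3*OD^3
#'
#' @param coefficients numeric length 4, `c(c0, c1, c2, c3)`.
#' @param channel `"R"`, `"G"` or `"B"`.
#' @param dose_range fitted/valid dose range in Gy.
#' @param od_range OD span the fit covers.
#' @param rms_residual rms fit residual in Gy.
#' @param monotone logical: is the curve strictly monotone in OD over
#'   `od_range` (checked numerically on fitting)?
#' @export
calibration_curve <- function(coefficients, channel = c("R", "G", "B"),
                              dose_range, od_range, rms_residual = 0,
                              monotone = TRUE) {
  channel <- match.arg(channel)
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != 4L || any(!is.finite(coefficients)))
    stop("need 4 finite polynomial coefficients")
  structure(list(coefficients = coefficients, channel = channel,
                 dose_range = as.numeric(dose_range),
                 od_range = as.numeric(od_range),
                 rms_residual = rms_residual, monotone = monotone),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> channel %s: dose = %+.4g %+.4g*OD %+.4g*OD^2 %+.4g*OD^3\n",
              x$channel, x$coefficients[1], x$coefficients[2],
              x$coefficients[3], x$coefficients[4]))
  cat(sprintf("  valid dose [%.3g, %.3g] Gy, OD span [%.3g, %.3g], rms %.2e Gy, monotone: %s\n",
              x$dose_range[1], x$dose_range[2], x$od_range[1], x$od_range[2],
              x$rms_residual, x$monotone))
  invisible(x)
}

eval_calibration <- function(curve, od) {
  c_ <- curve$coefficients
  c_[1] + od * (c_[2] + od * (c_[3] + od * c_[4]))
}

#' A plausible EBT3-like red-channel truth curve
#'
#' Strictly monotone over OD 0 to 1 (derivative 5.2 + 1.6 OD + 4.5 OD^2 > 0),
#' with near-zero dose at the unexposed base density (~0.18 OD). Used as the
#' default ground truth of the synthetic film-scan generator.
#'
#' @return a [calibration_curve].
#' @export
default_calibration_truth <- function() {
  calibration_curve(c(-1.0, 5.2, 0.8, 1.5), channel = "R",
                    dose_range = c(0, 4.5), od_range = c(0.1, 1.0))
}

# OD at which the curve gives `dose` (numeric inversion on the OD span)
invert_calibration <- function(curve, dose) {
  f <- function(od) eval_calibration(curve, od) - dose
  lo <- curve$od_range[1]; hi <- curve$od_range[2]
  # widen a little so doses at the range edges still bracket
  lo2 <- lo - 0.5 * (hi - lo); hi2 <- hi + 0.5 * (hi - lo)
  stats::uniroot(f, c(lo2, hi2), tol = 1e-12)$root
}

#' Convert a scanned transmission channel to optical density
#'
#' `OD = log10(i0 / pixel)` with `i0` a per-scan reference transmission
#' value (e.g. the mean reading of an unexposed film region), which removes
#' scanner lamp drift to first order. Pixel values are clipped below at 1;
#' saturated pixels (65535) are flagged in the returned mask.
#'
#' @param scan_channel a [dose_plane] of 16-bit channel readings.
#' @param i0 reference transmission value (> 0).
#' @return a [dose_plane] with quantity `"od"`; attribute `"saturated"`
#'   holds a logical matrix marking saturated input pixels.
#' @export
compute_od <- function(scan_channel, i0) {
  stopifnot(is_dose_plane(scan_channel))
  if (!is.numeric(i0) || length(i0) != 1L || i0 <= 0)
    stop("i0 must be a single positive number")
  px <- pmax(scan_channel$values, 1)
  od <- log10(i0 / px)
  out <- dose_plane(pmax(od, 0), scan_channel$spacing, scan_channel$origin,
                    quantity = "od")
  attr(out, "saturated") <- scan_channel$values >= 65535
  out
}

#' Fit a cubic calibration curve (dose as a function of OD)
#'
#' Least-squares cubic through the (OD, dose) calibration points, fitted in
#' the dose-from-OD direction. The fit records its rms residual and a
#' numerical monotonicity check over the fitted OD span; a non-monotone fit
#' is flagged with a warning, never silently.
#'
#' @param od_means patch-mean OD values (>= 4 distinct).
#' @param doses delivered patch doses in Gy, same length.
#' @param channel colour channel being fitted.
#' @return a [calibration_curve].
#' @export
fit_calibration <- function(od_means, doses, channel = c("R", "G", "B")) {
  channel <- match.arg(channel)
  od_means <- as.numeric(od_means); doses <- as.numeric(doses)
  if (length(od_means) != length(doses))
    stop("od_means and doses must have equal length")
  if (length(unique(signif(od_means, 12))) < 4L)
    stop("need at least 4 distinct OD values for a cubic fit")
  dup <- duplicated(od_means) | duplicated(od_means, fromLast = TRUE)
  if (any(dup)) {
    for (u in unique(od_means[dup]))
      if (length(unique(doses[od_means == u])) > 1L)
        stop("inconsistent calibration data: duplicate OD ", signif(u, 6),
             " maps to different doses")
  }
  X <- outer(od_means, 0:3, `^`)
  qr_ <- qr(X)
  if (qr_$rank < 4L) stop("rank-deficient calibration design matrix")
  cf <- qr.coef(qr_, doses)
  resid <- doses - X %*% cf
  rms <- sqrt(mean(resid^2))
  span <- range(od_means)
  grid <- seq(span[1], span[2], length.out = 257)
  deriv <- cf[2] + 2 * cf[3] * grid + 3 * cf[4] * grid^2
  mono <- all(deriv > 0) || all(deriv < 0)
  if (!mono)
    warning("fitted calibration curve is not monotone over the OD span")
  calibration_curve(cf, channel = channel,
                    dose_range = range(doses), od_range = span,
                    rms_residual = rms, monotone = mono)
}

#' Map an OD plane to dose through a calibration curve
#'
#' Per-pixel polynomial evaluation; pixels whose mapped dose falls outside
#' the curve's valid dose range are flagged in the `"out_of_range"`
#' attribute mask (with a small relative margin), not altered.
#'
#' @param curve a [calibration_curve].
#' @param od_plane a [dose_plane] with quantity `"od"`.
#' @return a [dose_plane] in Gy (quantity `"dose"`).
#' @export
apply_calibration <- function(curve, od_plane) {
  stopifnot(inherits(curve, "calibration_curve"), is_dose_plane(od_plane))
  if (od_plane$quantity != "od")
    stop("apply_calibration expects an OD plane")
  dose <- eval_calibration(curve, od_plane$values)
  margin <- 0.05 * diff(curve$dose_range)
  mask <- dose < curve$dose_range[1] - margin |
    dose > curve$dose_range[2] + margin
  out <- dose_plane(pmax(dose, 0), od_plane$spacing, od_plane$origin,
                    quantity = "dose")
  attr(out, "out_of_range") <- mask
  out
}

#' Save / load a calibration curve as JSON
#'
#' @param curve a [calibration_curve].
#' @param path JSON file path.
#' @return `path` / a [calibration_curve].
#' @export
write_calibration <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  jsonlite::write_json(unclass(curve), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_curve(x$coefficients, channel = x$channel,
                    dose_range = x$dose_range, od_range = x$od_range,
                    rms_residual = x$rms_residual, monotone = x$monotone)
}

#' Register a film dose plane to a planned dose plane
#'
#' Exhaustive search over rigid transforms (translation up to +/-10 mm,
#' rotation up to +/-5 degrees about the plane centre) maximizing the
#' normalized cross-correlation between the film plane resampled onto the
#' plan grid and the plan, followed by a finer local refinement. Fully
#' deterministic. A flat correlation surface (uniform images) is a
#' degenerate-registration error.
#'
#' @param film_dose,plan_dose [dose_plane]s in Gy with overlapping extent.
#' @param max_shift translation search bound in mm.
#' @param max_rot rotation search bound in degrees.
#' @param coarse_step,coarse_rot_step coarse grid steps (mm, deg).
#' @return list of class `registration_transform` with `translation`
#'   (x, y mm: film coordinates + translation match the plan), `rotation`
#'   (deg) and the achieved `correlation`.
#' @export
register_planes <- function(film_dose, plan_dose, max_shift = 10, max_rot = 5,
                            coarse_step = 1, coarse_rot_step = 1) {
  stopifnot(is_dose_plane(film_dose), is_dose_plane(plan_dose))
  ax <- plane_axes(plan_dose)
  g <- expand.grid(y = ax$y, x = ax$x)
  centre <- c(mean(range(plane_axes(film_dose)$y)),
              mean(range(plane_axes(film_dose)$x)))
  score <- function(tx, ty, rot) {
    th <- rot * pi / 180
    # plan-grid point minus candidate translation, rotated back into film frame
    xr <- g$x - tx - centre[2]; yr <- g$y - ty - centre[1]
    xs <- centre[2] + cos(th) * xr + sin(th) * yr
    ys <- centre[1] - sin(th) * xr + cos(th) * yr
    fv <- plane_interp(film_dose, ys, xs)
    ok <- !is.na(fv)
    if (sum(ok) < 16) return(NA_real_)
    a <- fv[ok]; b <- g$plan[ok]
    sa <- stats::sd(a); sb <- stats::sd(b)
    if (sa < 1e-12 || sb < 1e-12) return(NA_real_)
    mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
  }
  g$plan <- as.vector(plan_dose$values)
  search <- function(txs, tys, rots) {
    best <- c(NA, NA, NA, -Inf)
    for (rot in rots) for (tx in txs) for (ty in tys) {
      s <- score(tx, ty, rot)
      if (!is.na(s) && s > best[4]) best <- c(tx, ty, rot, s)
    }
    best
  }
  b <- search(seq(-max_shift, max_shift, coarse_step),
              seq(-max_shift, max_shift, coarse_step),
              seq(-max_rot, max_rot, coarse_rot_step))
  if (!is.finite(b[4]))
    stop("degenerate registration: no overlap or uniform images")
  # separable sub-grid refinement: translation at the coarse-best rotation,
  # then rotation at the refined translation (the NCC surface is smooth and
  # near-separable close to the optimum)
  b2 <- search(b[1] + seq(-coarse_step, coarse_step, coarse_step / 10),
               b[2] + seq(-coarse_step, coarse_step, coarse_step / 10),
               b[3])
  b2 <- search(b2[1], b2[2],
               b2[3] + seq(-coarse_rot_step, coarse_rot_step, coarse_rot_step / 20))
  if (b2[4] - b[4] < 1e-12 && b2[4] < 0.2)
    stop("degenerate registration: flat correlation surface")
  structure(list(translation = c(b2[1], b2[2]), rotation = b2[3],
                 correlation = b2[4]),
            class = "registration_transform")
}
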