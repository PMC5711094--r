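# 2D gamma-index evaluation: for each reference pixel, the minimum over
# nearby evaluated-plane positions of the combined dose-difference /
# distance-to-agreement metric
#   gamma(r) = min_e sqrt( (D_e - D_r)^2 / dD^2 + |r_e - r|^2 / dta^2 ).
# The evaluated plane is sampled bilinearly on a disc of candidate shifts;
# candidates are visited in order of increasing distance so the search can
# stop as soon as the distance term alone exceeds the worst current gamma.

#' Gamma evaluation criteria
#'
#' @param dose_tolerance dose criterion in % of the normalization dose
#'   (default 3).
#' @param dta distance-to-agreement criterion in mm (default 3).
#' @param normalization `"global-max"` (percentage of the reference plane
#'   maximum, the TG-119-era clinical convention) or `"local"` (percentage
#'   of the local reference dose).
#' @param low_dose_threshold pixels with reference dose below this % of the
#'   reference maximum are excluded from the passing rate (default 10).
#' @export
gamma_criteria <- function(dose_tolerance = 3, dta = 3,
                           normalization = c("global-max", "local"),
                           low_dose_threshold = 10) {
  normalization <- match.arg(normalization)
  if (dose_tolerance <= 0 || dta <= 0 || low_dose_threshold <= 0)
    stop("criteria must be strictly positive")
  if (low_dose_threshold >= 100)
    stop("low_dose_threshold must be below 100%")
  structure(list(dose_tolerance = dose_tolerance, dta = dta,
                 normalization = normalization,
                 low_dose_threshold = low_dose_threshold),
            class = "gamma_criteria")
}

#' Compute the 2D gamma map of an evaluated plane against a reference
#'
#' @param reference,evaluated [dose_plane]s in Gy with overlapping physical
#'   extent (they need not share a grid).
#' @param criteria a [gamma_criteria].
#' @param search_factor search radius as a multiple of `dta` (default 3).
#' @param step_fraction candidate-shift step as a fraction of `dta`
#'   (default 0.05, i.e. dta/20; the discretization error of the distance
#'   term scales with the step, and dta/20 keeps it below ~0.02 in gamma).
#' @return object of class `gamma_result`: `gamma` (a [dose_plane] with
#'   quantity `"gamma"`; `NA` where the evaluated plane provides no data),
#'   `passing_rate` (% of evaluated pixels with gamma <= 1, one decimal),
#'   `n_evaluated`, `mask` (logical matrix of evaluated pixels),
#'   `criteria`.
#' @export
gamma_map <- function(reference, evaluated, criteria = gamma_criteria(),
                      search_factor = 3, step_fraction = 0.05) {
  stopifnot(is_dose_plane(reference), is_dose_plane(evaluated),
            inherits(criteria, "gamma_criteria"))
  rax <- plane_axes(reference); eax <- plane_axes(evaluated)
  if (min(rax$x) > max(eax$x) || max(rax$x) < min(eax$x) ||
      min(rax$y) > max(eax$y) || max(rax$y) < min(eax$y))
    stop("reference and evaluated planes do not overlap")
  refv <- reference$values
  norm_base <- max(refv)
  if (norm_base <= 0) stop("reference plane has no positive dose")
  mask <- refv >= criteria$low_dose_threshold / 100 * norm_base
  if (!any(mask)) stop("empty evaluation region: all pixels below threshold")
  dD <- if (criteria$normalization == "global-max")
    matrix(criteria$dose_tolerance / 100 * norm_base, nrow(refv), ncol(refv))
  else pmax(criteria$dose_tolerance / 100 * refv, 1e-9 * norm_base)

  dta <- criteria$dta
  step <- dta * step_fraction
  radius <- search_factor * dta
  k <- seq(-floor(radius / step), floor(radius / step)) * step
  offs <- expand.grid(dx = k, dy = k)
  offs$d2 <- offs$dx^2 + offs$dy^2
  offs <- offs[offs$d2 <= radius^2 + 1e-12, ]
  offs <- offs[order(offs$d2), ]

  g <- expand.grid(y = rax$y, x = rax$x)
  best <- matrix(Inf, nrow(refv), ncol(refv))
  for (m in seq_len(nrow(offs))) {
    dist_term <- offs$d2[m] / dta^2
    if (m > 1L && all(is.finite(best)) && dist_term >= max(best)) break
    ev <- plane_interp(evaluated, g$y + offs$dy[m], g$x + offs$dx[m])
    ok <- !is.na(ev)
    if (!any(ok)) next
    cand <- ((ev[ok] - refv[ok])^2) / (dD[ok]^2) + dist_term
    sel <- which(ok)[cand < best[ok]]
    best[sel] <- (((ev - refv)^2) / (dD^2) + dist_term)[sel]
  }
  gm <- sqrt(best)
  gm[!is.finite(gm)] <- NA_real_
  mask <- mask & !is.na(gm)
  if (!any(mask)) stop("empty evaluation region: no evaluated data available")
  gplane <- dose_plane_gamma(gm, reference$spacing, reference$origin)
  res <- structure(list(gamma = gplane, mask = mask, criteria = criteria,
                        n_evaluated = sum(mask)),
                   class = "gamma_result")
  res$passing_rate <- passing_rate(res)
  res
}

# gamma maps may carry NA where the evaluated plane has no data; bypass the
# finiteness check of the public constructor
dose_plane_gamma <- function(values, spacing, origin) {
  p <- dose_plane(ifelse(is.na(values), 0, values), spacing, origin,
                  quantity = "gamma")
  p$values <- values
  p
}

#' Gamma passing rate over a region of interest
#'
#' Percentage of evaluated (above-threshold) pixels with gamma <= 1,
#' reported to one decimal.
#'
#' @param result a `gamma_result`.
#' @param roi optional [qa_roi]; default uses the whole plane.
#' @return passing rate in %.
#' @export
passing_rate <- function(result, roi = NULL) {
  stopifnot(inherits(result, "gamma_result"))
  sel <- result$mask
  if (!is.null(roi)) {
    idx <- roi_pixel_index(result$gamma, roi)
    roi_mask <- matrix(FALSE, nrow(sel), ncol(sel))
    roi_mask[idx$rows, idx$cols] <- TRUE
    sel <- sel & roi_mask
  }
  if (!any(sel)) stop("no evaluated pixels inside the ROI")
  g <- result$gamma$values[sel]
  # tiny tolerance so doses exactly at the criterion (gamma == 1 up to
  # floating point) count as passing
  round_half_up(100 * mean(g <= 1 + 1e-9), 1)
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %s%%/%g mm (%s, threshold %g%%): passing rate %.1f%% over %d pixels\n",
              format(x$criteria$dose_tolerance), x$criteria$dta,
              x$criteria$normalization, x$criteria$low_dose_threshold,
              x$passing_rate, x$n_evaluated))
  invisible(x)
}
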