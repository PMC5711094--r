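# Synthetic acquisition generators: beam planes, picket-fence images, DR/GS
# and LS/DR strip patterns, film calibration scans, and per-case measurement
# tables. Every generator is a pure function of (spec, seed) and returns its
# ground truth alongside the data, so tests never re-derive truth from the
# generated image.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single number")
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Photon beam model (flattened or flattening-filter-free)
#'
#' A deliberately simple fluence model: a square field of size `field_size`
#' with a linear-ramp penumbra of half-width `penumbra` mm on each edge (the
#' interior is exactly flat for FF), multiplied for FFF mode by the
#' forward-peaked radial factor `1 - k * r` (clipped at zero), which mimics
#' the sharp off-axis falloff of an unflattened beam. The default `k` puts
#' the 100 mm off-axis value at ~70% of the central axis.
#'
#' @param mode `"FF"` or `"FFF"`.
#' @param field_size square field side in mm.
#' @param penumbra penumbra half-width in mm (> 0).
#' @param k FFF radial falloff slope per mm (>= 0); forced to 0 for FF.
#' @param peak central-axis value (arbitrary reading units).
#' @return object of class `beam_model`.
#' @export
beam_model <- function(mode = c("FF", "FFF"), field_size = 140,
                       penumbra = 3, k = 0.003, peak = 1) {
  mode <- match.arg(mode)
  if (penumbra <= 0) stop("penumbra must be > 0")
  if (mode == "FF") k <- 0
  if (k < 0) stop("k must be >= 0")
  if (field_size <= 0 || peak <= 0) stop("field_size and peak must be > 0")
  structure(list(mode = mode, field_size = field_size, penumbra = penumbra,
                 k = k, peak = peak), class = "beam_model")
}

beam_envelope_1d <- function(x, half, penumbra) {
  pmin(1, pmax(0, (half + penumbra - abs(x)) / (2 * penumbra)))
}

beam_values <- function(model, y, x) {
  half <- model$field_size / 2
  ex <- beam_envelope_1d(x, half, model$penumbra)
  ey <- beam_envelope_1d(y, half, model$penumbra)
  env <- outer(ey, ex)
  if (model$mode == "FFF") {
    r <- sqrt(outer(y^2, x^2, `+`))
    env <- env * pmax(0, 1 - model$k * r)
  }
  model$peak * env
}

#' Generate an open-field beam plane
#'
#' @param model a [beam_model].
#' @param spacing pixel pitch in mm.
#' @param extent grid side length in mm; default covers the field plus
#'   penumbra and margin.
#' @param noise_sd multiplicative Gaussian noise SD (fraction of the local
#'   value); 0 for a noiseless plane.
#' @param seed RNG seed (the global RNG state is restored afterwards).
#' @return a [dose_plane] with quantity `"reading"`, origin at plane centre.
#' @export
gen_beam_plane <- function(model, spacing = 1, extent = NULL, noise_sd = 0,
                           seed = NULL) {
  stopifnot(inherits(model, "beam_model"), spacing > 0, noise_sd >= 0)
  if (is.null(extent)) extent <- model$field_size + 4 * model$penumbra + 10
  if (extent < model$field_size) stop("field does not fit the grid")
  n <- max(2L, floor(extent / spacing) + 1L)
  coord <- (seq_len(n) - (n + 1) / 2) * spacing
  vals <- beam_values(model, coord, coord)
  if (noise_sd > 0)
    vals <- with_seed(seed, vals * (1 + matrix(stats::rnorm(n * n, 0, noise_sd), n)))
  dose_plane(pmax(vals, 0), spacing, quantity = "reading")
}

#' Picket-fence test specification
#'
#' @param gap picket (transmitted slit) width in mm, default 1.0.
#' @param spacing centre-to-centre picket spacing in mm (> gap).
#' @param n_pickets number of pickets.
#' @param offsets per-picket position offsets in mm (recycled); injects
#'   deliberate leaf-position errors with known truth.
#' @param blur_sigma Gaussian blur of the slit edges in mm (source size +
#'   detector blur), >= 0.
#' @param noise_sd multiplicative noise SD (fraction).
#' @export
picket_fence_spec <- function(gap = 1.0, spacing = 15, n_pickets = 5,
                              offsets = 0, blur_sigma = 1.0, noise_sd = 0) {
  if (gap <= 0) stop("gap must be > 0")
  if (spacing <= gap) stop("picket spacing must exceed the gap width")
  if (n_pickets < 1) stop("need at least one picket")
  offsets <- rep_len(as.numeric(offsets), n_pickets)
  if (blur_sigma < 0 || noise_sd < 0) stop("blur_sigma and noise_sd must be >= 0")
  structure(list(gap = gap, spacing = spacing, n_pickets = n_pickets,
                 offsets = offsets, blur_sigma = blur_sigma,
                 noise_sd = noise_sd), class = "picket_fence_spec")
}

#' Generate a picket-fence image with known picket positions
#'
#' Pickets are narrow transmitted slits in an otherwise closed MLC bank,
#' modelled as blurred boxcar windows over a small leakage floor and
#' multiplied by the beam plane. The returned truth contains the exact
#' picket centres including any injected offsets.
#'
#' @param spec a [picket_fence_spec].
#' @param beam a [beam_model].
#' @param spacing detector pixel pitch in mm (default 0.25, EPID-like).
#' @param seed RNG seed for the noise.
#' @return list with `plane` (a [dose_plane]), `truth` (picket centre
#'   positions, mm) and `spec`.
#' @export
gen_picket_fence <- function(spec, beam, spacing = 0.25, seed = NULL) {
  stopifnot(inherits(spec, "picket_fence_spec"), inherits(beam, "beam_model"))
  centres <- (seq_len(spec$n_pickets) - (spec$n_pickets + 1) / 2) *
    spec$spacing + spec$offsets
  if (any(diff(sort(centres)) <= spec$gap))
    stop("pickets overlap after applying offsets")
  if (max(abs(centres)) + spec$gap / 2 > beam$field_size / 2)
    stop("pickets do not fit inside the field")
  open <- gen_beam_plane(beam, spacing = spacing)
  ax <- plane_axes(open)
  leak <- 0.02
  s <- spec$blur_sigma
  window <- rep(0, length(ax$x))
  for (p in centres) {
    lo <- p - spec$gap / 2; hi <- p + spec$gap / 2
    w <- if (s > 0) stats::pnorm((ax$x - lo) / s) - stats::pnorm((ax$x - hi) / s)
         else as.numeric(ax$x >= lo & ax$x < hi)
    window <- window + w
  }
  trans <- leak + (1 - leak) * pmin(window, 1)
  vals <- open$values * matrix(trans, nrow = nrow(open$values),
                               ncol = ncol(open$values), byrow = TRUE)
  if (spec$noise_sd > 0)
    vals <- with_seed(seed, vals * (1 + matrix(
      stats::rnorm(length(vals), 0, spec$noise_sd), nrow(vals))))
  list(plane = dose_plane(pmax(vals, 0), spacing, quantity = "reading"),
       truth = centres, spec = spec)
}

#' Strip-pattern specification (DR/GS and LS/DR uniformity tests)
#'
#' @param n_strips number of equal-dose strips (7 for the dose-rate /
#'   gantry-speed test, 4 for leaf-speed / dose-rate).
#' @param strip_width strip width in mm (18 mm for DR/GS).
#' @param scales per-strip true fluence scale factors (> 0, recycled);
#'   deviations injected here are the ground truth the strip analysis must
#'   recover.
#' @param noise_sd multiplicative noise SD (fraction).
#' @export
strip_pattern_spec <- function(n_strips = 7, strip_width = 18,
                               scales = 1, noise_sd = 0) {
  if (n_strips < 2) stop("need at least two strips")
  if (strip_width <= 0) stop("strip_width must be > 0")
  scales <- rep_len(as.numeric(scales), n_strips)
  if (any(scales <= 0)) stop("scale factors must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_strips = n_strips, strip_width = strip_width,
                 scales = scales, noise_sd = noise_sd),
            class = "strip_pattern_spec")
}

#' Generate a strip-test plane and its matched open field
#'
#' The strip plane equals the open plane multiplied by the per-strip scale
#' factor inside each strip (2% leakage outside), plus multiplicative noise;
#' both planes share geometry so that the open-field correction cancels the
#' beam profile exactly in the noiseless case.
#'
#' @param spec a [strip_pattern_spec].
#' @param beam a [beam_model]; its field must cover the strip block.
#' @param spacing pixel pitch in mm.
#' @param seed RNG seed.
#' @return list with `strip` and `open` ([dose_plane]s), `rois` (per-strip
#'   [qa_roi]s over the central 60% of each strip), `scales`,
#'   `positions_cm` (strip centres in cm).
#' @export
gen_strip_pair <- function(spec, beam, spacing = 1, seed = NULL) {
  stopifnot(inherits(spec, "strip_pattern_spec"), inherits(beam, "beam_model"))
  block <- spec$n_strips * spec$strip_width
  if (block > beam$field_size)
    stop("strip block wider than the beam field")
  open <- gen_beam_plane(beam, spacing = spacing)
  ax <- plane_axes(open)
  edges <- -block / 2 + (0:spec$n_strips) * spec$strip_width
  idx <- findInterval(ax$x, edges, rightmost.closed = TRUE)
  scale_x <- ifelse(idx >= 1 & idx <= spec$n_strips,
                    spec$scales[pmax(idx, 1)], 0.02)
  vals <- open$values * matrix(scale_x, nrow = nrow(open$values),
                               ncol = ncol(open$values), byrow = TRUE)
  open_vals <- open$values
  if (spec$noise_sd > 0) {
    vals <- with_seed(seed, {
      v <- vals * (1 + matrix(stats::rnorm(length(vals), 0, spec$noise_sd),
                              nrow(vals)))
      ov <- open_vals * (1 + matrix(stats::rnorm(length(open_vals), 0,
                                                 spec$noise_sd), nrow(open_vals)))
      list(v, ov)
    })
    open_vals <- vals[[2]]; vals <- vals[[1]]
  }
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  margin <- spec$strip_width * 0.2          # central 60% of each strip
  ylim <- beam$field_size * 0.3
  rois <- lapply(centres, function(cx)
    qa_roi(cx - spec$strip_width / 2 + margin, cx + spec$strip_width / 2 - margin,
           -ylim, ylim))
  list(strip = dose_plane(pmax(vals, 0), spacing, quantity = "reading"),
       open = dose_plane(pmax(open_vals, 0), spacing, quantity = "reading"),
       rois = rois, scales = spec$scales, positions_cm = centres / 10)
}

#' Generate a synthetic film calibration scan
#'
#' Emulates a flatbed transmission scan of a 3 x 3 grid of square
#' calibration patches: each patch's optical density is obtained by
#' inverting the true calibration curve at its nominal dose, noise is added
#' on OD (additive Gaussian with SD `noise_sd` times the local OD), and the
#' 16-bit channel reading is `i0 * 10^-OD`. The green and blue channels
#' carry scaled copies of the red-channel OD (relative sensitivities 0.75
#' and 0.5), emulating the decreasing dose response of those channels.
#'
#' @param doses patch doses in Gy (9 values for the standard pattern).
#' @param true_curve a [calibration_curve] mapping OD to dose for the
#'   fitted channel; default [default_calibration_truth()].
#' @param patch_size patch side in mm.
#' @param dpi scan resolution (75 dpi standard protocol).
#' @param noise_sd fractional OD noise SD.
#' @param i0 unattenuated (reference) transmission value.
#' @param seed RNG seed.
#' @return list with `channels` (R/G/B [dose_plane]s of 16-bit readings),
#'   `rois` (patch [qa_roi]s, central 60%), `doses`, `od_truth` (red-channel
#'   OD per patch), `i0`, `curve`, `dpi`.
#' @export
gen_film_scan <- function(doses = seq(0.4, 3.2, length.out = 9),
                          true_curve = default_calibration_truth(),
                          patch_size = 20, dpi = 75, noise_sd = 0,
                          i0 = 60000, seed = NULL) {
  stopifnot(inherits(true_curve, "calibration_curve"),
            patch_size > 0, dpi > 0, noise_sd >= 0, i0 > 0)
  nd <- length(doses)
  od_patch <- vapply(doses, function(d) invert_calibration(true_curve, d), 0)
  lay <- film_patch_layout(nd, patch_size = patch_size)
  px <- 25.4 / dpi
  nx <- floor(lay$extent[2] / px) + 1L; ny <- floor(lay$extent[1] / px) + 1L
  xc <- (seq_len(nx) - (nx + 1) / 2) * px
  yc <- (seq_len(ny) - (ny + 1) / 2) * px
  base_od <- invert_calibration(true_curve, 0)
  od <- matrix(base_od, ny, nx)
  for (kk in seq_len(nd)) {
    inx <- abs(xc - lay$centres[kk, "x"]) < patch_size / 2
    iny <- abs(yc - lay$centres[kk, "y"]) < patch_size / 2
    od[iny, inx] <- od_patch[kk]
  }
  rois <- lay$rois
  sens <- c(R = 1, G = 0.75, B = 0.5)
  channels <- with_seed(seed, {
    lapply(sens, function(s) {
      od_ch <- od * s
      if (noise_sd > 0)
        od_ch <- od_ch + matrix(stats::rnorm(length(od_ch), 0, noise_sd),
                                ny) * od_ch
      # kept unquantized; 16-bit rounding happens only on TIFF export
      reading <- pmin(pmax(i0 * 10^(-od_ch), 1), 65535)
      dose_plane(reading, spacing = px, quantity = "reading")
    })
  })
  list(channels = channels, rois = rois, doses = doses, od_truth = od_patch,
       i0 = i0, curve = true_curve, dpi = dpi)
}

#' Standard film calibration patch layout
#'
#' Square patches on a row-major grid (3 x 3 for the standard nine-dose
#' pattern), `gap` mm apart with a `margin` mm border, centred on the scan
#' origin. Shared between the synthetic generator and the calibration CLI
#' so ROIs always match the delivered pattern.
#'
#' @param n_patches number of patches.
#' @param patch_size patch side in mm.
#' @param gap spacing between patches in mm.
#' @param margin border in mm.
#' @param roi_fraction central fraction of each patch used for sampling.
#' @return list with `rois` (list of [qa_roi]), `centres` (matrix with
#'   columns x, y in mm) and `extent` (height, width of the scan in mm).
#' @export
film_patch_layout <- function(n_patches = 9, patch_size = 20, gap = 5,
                              margin = 5, roi_fraction = 0.6) {
  ncols <- ceiling(sqrt(n_patches)); nrows <- ceiling(n_patches / ncols)
  w_mm <- ncols * patch_size + (ncols - 1) * gap + 2 * margin
  h_mm <- nrows * patch_size + (nrows - 1) * gap + 2 * margin
  m <- patch_size * (1 - roi_fraction) / 2
  centres <- t(vapply(seq_len(n_patches) - 1L, function(k) {
    r <- k %/% ncols; c_ <- k %% ncols
    c(x = -w_mm / 2 + margin + c_ * (patch_size + gap) + patch_size / 2,
      y = -h_mm / 2 + margin + r * (patch_size + gap) + patch_size / 2)
  }, c(x = 0, y = 0)))
  rois <- lapply(seq_len(n_patches), function(k)
    qa_roi(centres[k, "x"] - patch_size / 2 + m,
           centres[k, "x"] + patch_size / 2 - m,
           centres[k, "y"] - patch_size / 2 + m,
           centres[k, "y"] + patch_size / 2 - m))
  list(rois = rois, centres = centres, extent = c(h_mm, w_mm))
}

#' Per-case measurement-table specification
#'
#' The stated world for the point-dose statistics: per-case dose-difference
#' ratios are Normal(`bias`, `sd`) by construction, mirroring the TG-119
#' decomposition into systematic (mean) and random (SD) components. Defaults
#' match a well-commissioned machine: bias -0.002, SD 0.015 of prescription.
#'
#' @param n_cases number of cases.
#' @param bias systematic difference as a fraction of prescription.
#' @param sd random difference SD (>= 0), fraction of prescription.
#' @param prescription prescription dose in Gy.
#' @export
case_table_spec <- function(n_cases = 5, bias = -0.002, sd = 0.015,
                            prescription = 2) {
  if (n_cases < 1) stop("need at least one case")
  if (sd < 0) stop("sd must be >= 0")
  if (prescription <= 0) stop("prescription must be > 0")
  structure(list(n_cases = n_cases, bias = bias, sd = sd,
                 prescription = prescription), class = "case_table_spec")
}

#' Generate a per-case point-measurement table
#'
#' @param spec a [case_table_spec].
#' @param seed RNG seed.
#' @return data.frame with columns `case`, `measured`, `planned`,
#'   `prescription` (Gy); `(measured - planned)/prescription` is
#'   Normal(bias, sd) by construction.
#' @export
gen_case_table <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "case_table_spec"))
  diffs <- if (spec$sd == 0) rep(spec$bias, spec$n_cases)
           else with_seed(seed, stats::rnorm(spec$n_cases, spec$bias, spec$sd))
  planned <- rep(spec$prescription, spec$n_cases)
  data.frame(case = paste0("case", seq_len(spec$n_cases)),
             measured = planned + diffs * spec$prescription,
             planned = planned,
             prescription = rep(spec$prescription, spec$n_cases))
}

#' Generate a reference/evaluated plane pair for gamma testing
#'
#' The evaluated plane is the base plane scaled by `1 + dose_error` and
#' rigidly translated by `shift` (resampled bilinearly, edge-replicated).
#'
#' @param base a [dose_plane].
#' @param dose_error fractional dose error.
#' @param shift length-2 translation (x, y) in mm: a feature at x in the
#'   base appears at x + shift in the evaluated plane.
#' @return list with `reference` and `evaluated` planes.
#' @export
gen_plane_pair <- function(base, dose_error = 0, shift = c(0, 0)) {
  stopifnot(is_dose_plane(base), length(shift) == 2)
  ax <- plane_axes(base)
  g <- expand.grid(y = ax$y, x = ax$x)
  ys <- pmin(pmax(g$y - shift[2], min(ax$y)), max(ax$y))
  xs <- pmin(pmax(g$x - shift[1], min(ax$x)), max(ax$x))
  vals <- matrix(plane_interp(base, ys, xs), nrow = nrow(base$values))
  evaluated <- dose_plane((1 + dose_error) * vals, base$spacing, base$origin,
                          quantity = base$quantity)
  list(reference = base, evaluated = evaluated)
}
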