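# TG-119 commissioning statistics: point-dose difference ratios, confidence
# limits for point doses (|mean| + 1.96 sd) and gamma passing rates
# (100 - mean + 1.96 sd), per-energy aggregation, couch-transmission
# differences, and a combined report. SD is the sample SD (n - 1)
# throughout; that convention is what reproduces the reference tables.

#' Point-dose difference ratio
#'
#' `(measured - planned) / prescription`, the TG-119 definition; the
#' prescription dose in the denominator keeps low-dose points on the same
#' scale as the target points.
#'
#' @param measured,planned,prescription doses in Gy (vectorized);
#'   `prescription > 0`.
#' @return difference ratio(s) as fractions.
#' @export
dose_diff_ratio <- function(measured, planned, prescription) {
  if (any(prescription <= 0)) stop("prescription dose must be > 0")
  (measured - planned) / prescription
}

cl_record <- function(inputs, mean, sd, cl, flavor) {
  structure(list(inputs = inputs, mean = mean, sd = sd, cl = cl,
                 n = length(inputs), flavor = flavor), class = "cl_record")
}

#' @export
print.cl_record <- function(x, ...) {
  cat(sprintf("<cl_record> %s: n = %d, mean %.4g, sd %.4g, CL %.4g\n",
              x$flavor, x$n, x$mean, x$sd, x$cl))
  invisible(x)
}

#' TG-119 confidence limit for point-dose differences
#'
#' `CL = |mean| + 1.96 * sd` over the per-case difference ratios: the mean
#' captures the systematic deviation, 1.96 SD the random component, so that
#' ~95% of future differences fall within the limit.
#'
#' @param diffs per-case difference ratios (fractions), n >= 2.
#' @return a `cl_record` (flavor `"point"`).
#' @export
confidence_limit_point <- function(diffs) {
  diffs <- as.numeric(diffs)
  if (length(diffs) < 2L) stop("need at least two cases")
  m <- mean(diffs); s <- stats::sd(diffs)
  cl_record(diffs, m, s, abs(m) + 1.96 * s, "point")
}

#' TG-119 confidence limit for gamma passing rates
#'
#' `CL = 100 - mean + 1.96 * sd` over per-case passing rates in %.
#'
#' @param rates per-case gamma passing rates (%), n >= 2.
#' @return a `cl_record` (flavor `"gamma"`).
#' @export
confidence_limit_gamma <- function(rates) {
  rates <- as.numeric(rates)
  if (length(rates) < 2L) stop("need at least two cases")
  if (any(rates < 0 | rates > 100)) stop("passing rates must be in [0, 100]")
  m <- mean(rates); s <- stats::sd(rates)
  cl_record(rates, m, s, 100 - m + 1.96 * s, "gamma")
}

#' Aggregate per-energy confidence limits
#'
#' @param cls numeric vector of per-energy CL values (or a list of
#'   `cl_record`s).
#' @return list with `mean`, `sd` (sample), `min`, `max`, `n`.
#' @export
aggregate_cl <- function(cls) {
  if (is.list(cls)) cls <- vapply(cls, function(x) x$cl, 0)
  cls <- as.numeric(cls)
  if (length(cls) < 1L) stop("no confidence limits to aggregate")
  list(mean = mean(cls),
       sd = if (length(cls) >= 2L) stats::sd(cls) else NA_real_,
       min = min(cls), max = max(cls), n = length(cls))
}

#' Couch transmission percent difference
#'
#' `(measured - calculated) / calculated * 100`: how far the measured couch
#' transmission deviates from the treatment-planning-system calculation.
#'
#' @param calculated,measured transmission factors (fractions, vectorized).
#' @return percent difference(s).
#' @export
couch_transmission_diff <- function(calculated, measured) {
  if (any(calculated <= 0)) stop("calculated transmission must be > 0")
  (measured - calculated) / calculated * 100
}

normalize_point_table <- function(point_table) {
  pt <- as.data.frame(point_table)
  need <- c("technique", "energy", "region")
  if (!all(need %in% names(pt)))
    stop("point table needs columns technique, energy, region")
  if (!"diff" %in% names(pt)) {
    if (all(c("measured", "planned", "prescription") %in% names(pt))) {
      pt$diff <- dose_diff_ratio(pt$measured, pt$planned, pt$prescription)
    } else if ("diff_pct" %in% names(pt)) {
      pt$diff <- pt$diff_pct / 100
    } else stop("point table needs diff, diff_pct, or measured/planned/prescription")
  }
  pt
}

#' Build a TG-119 commissioning report
#'
#' Recomputes every per-technique x energy x region confidence limit from
#' per-case inputs, aggregates them abstract-style (mean, SD, range over
#' energies), evaluates the point CLs against baseline action levels, and
#' appends couch-transmission statistics when provided.
#'
#' @param point_table data.frame of per-case point measurements: columns
#'   `case`, `technique`, `energy`, `region` and either `diff` (fraction),
#'   `diff_pct`, or `measured`/`planned`/`prescription` (Gy).
#' @param gamma_table data.frame of per-case gamma passing rates: columns
#'   `case`, `technique`, `energy`, `region`, `rate` (%).
#' @param couch_table optional data.frame with `energy`, `section`,
#'   `calculated`, `measured` transmission factors.
#' @param baselines named action levels for the point CLs by region;
#'   defaults are the multi-institution TG-119 averages (0.045 high-dose,
#'   0.047 low-dose).
#' @return object of class `tg119_report`: data.frames `point` and `gamma`
#'   (per technique/energy/region: n, mean, sd, cl, and for points a pass
#'   flag), `point_aggregate` and `gamma_aggregate` (per technique/region),
#'   and `couch` (per-energy %diff plus per-section averages) when given.
#' @export
build_report <- function(point_table, gamma_table, couch_table = NULL,
                         baselines = c(high = 0.045, low = 0.047)) {
  if (is.null(point_table) || nrow(as.data.frame(point_table)) == 0L)
    stop("empty point table")
  if (is.null(gamma_table) || nrow(as.data.frame(gamma_table)) == 0L)
    stop("empty gamma table")
  pt <- normalize_point_table(point_table)
  gt <- as.data.frame(gamma_table)
  if (!all(c("technique", "energy", "region", "rate") %in% names(gt)))
    stop("gamma table needs columns technique, energy, region, rate")

  point <- do.call(rbind, lapply(
    split(pt, pt[c("technique", "energy", "region")], drop = TRUE),
    function(d) {
      r <- confidence_limit_point(d$diff)
      data.frame(technique = d$technique[1], energy = d$energy[1],
                 region = d$region[1], n = r$n, mean = r$mean, sd = r$sd,
                 cl = r$cl,
                 pass = r$cl <= baselines[[as.character(d$region[1])]])
    }))
  gamma <- do.call(rbind, lapply(
    split(gt, gt[c("technique", "energy", "region")], drop = TRUE),
    function(d) {
      r <- confidence_limit_gamma(d$rate)
      data.frame(technique = d$technique[1], energy = d$energy[1],
                 region = d$region[1], n = r$n, mean = r$mean, sd = r$sd,
                 cl = r$cl)
    }))
  rownames(point) <- rownames(gamma) <- NULL

  agg <- function(df) {
    out <- do.call(rbind, lapply(
      split(df, df[c("technique", "region")], drop = TRUE),
      function(d) {
        a <- aggregate_cl(d$cl)
        data.frame(technique = d$technique[1], region = d$region[1],
                   n_energies = a$n, cl_mean = a$mean, cl_sd = a$sd,
                   cl_min = a$min, cl_max = a$max)
      }))
    rownames(out) <- NULL
    out
  }

  rep_ <- list(point = point, gamma = gamma,
               point_aggregate = agg(point), gamma_aggregate = agg(gamma),
               baselines = baselines)
  if (!is.null(couch_table)) {
    ct <- as.data.frame(couch_table)
    if (!all(c("energy", "section", "calculated", "measured") %in% names(ct)))
      stop("couch table needs columns energy, section, calculated, measured")
    ct$diff_pct <- couch_transmission_diff(ct$calculated, ct$measured)
    avg <- do.call(rbind, lapply(split(ct, ct$section), function(d)
      data.frame(section = d$section[1], mean_diff_pct = mean(d$diff_pct))))
    rownames(avg) <- NULL
    rep_$couch <- ct
    rep_$couch_average <- avg
  }
  structure(rep_, class = "tg119_report")
}

#' @export
print.tg119_report <- function(x, ...) {
  cat("<tg119_report>\n\nPoint-dose confidence limits:\n")
  p <- x$point
  p$cl <- round_half_up(p$cl, 3)
  print(p, digits = 3)
  cat("\nGamma confidence limits (%):\n")
  g <- x$gamma
  g$cl <- round_half_up(g$cl, 1)
  print(g, digits = 3)
  cat("\nAggregates over energies (point):\n")
  print(x$point_aggregate, digits = 3)
  cat("\nAggregates over energies (gamma):\n")
  print(x$gamma_aggregate, digits = 3)
  if (!is.null(x$couch)) {
    cat("\nCouch transmission %diff averages:\n")
    print(x$couch_average, digits = 3)
  }
  invisible(x)
}

#' Bundled TrueBeam TG-119 commissioning reference dataset
#'
#' Plain-CSV tables from a published TrueBeam commissioning exercise run to
#' the TG-119 protocol, shipped with the package as reference inputs:
#' per-case point-dose difference ratios (high- and low-dose points, five
#' energies, IMRT and RapidArc), per-case 3%/3 mm gamma passing rates,
#' couch transmission factors, and the DR/GS and LS/DR strip-test readings
#' with their matched open fields.
#'
#' @param name one of `"point_high"`, `"point_low"`, `"gamma_high"`,
#'   `"gamma_low"`, `"couch"`, `"strips"`.
#' @return a data.frame.
#' @export
qa_reference_table <- function(name = c("point_high", "point_low",
                                        "gamma_high", "gamma_low",
                                        "couch", "strips")) {
  name <- match.arg(name)
  file <- c(point_high = "tg119_point_diff_high.csv",
            point_low = "tg119_point_diff_low.csv",
            gamma_high = "tg119_gamma_high.csv",
            gamma_low = "tg119_gamma_low.csv",
            couch = "couch_transmission.csv",
            strips = "strip_tests.csv")[[name]]
  path <- system.file("extdata", file, package = "linacqa", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
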