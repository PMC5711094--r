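test_that("dose_diff_ratio follows the TG-119 definition", {
  expect_equal(dose_diff_ratio(2.0, 2.0, 2.0), 0)
  expect_equal(dose_diff_ratio(2.04, 2.00, 2.00), 0.020)
  expect_error(dose_diff_ratio(1, 1, 0), "> 0")
})

test_that("point confidence limits reproduce the frozen reference columns", {
  # per-case difference columns whose printed CLs are 0.022, 0.036, 0.024
  r1 <- confidence_limit_point(c(0.015, 0.005, 0.001, 0.010, 0.016))
  expect_equal(round_half_up(r1$cl, 3), 0.022)
  r2 <- confidence_limit_point(c(0.001, -0.022, -0.021, -0.021, -0.000))
  expect_equal(round_half_up(r2$cl, 3), 0.036)
  r3 <- confidence_limit_point(c(-0.001, -0.011, 0.018, -0.004, -0.009, -0.010))
  expect_equal(round_half_up(r3$cl, 3), 0.024)
  # constant differences: sigma = 0, CL = |d|
  expect_equal(confidence_limit_point(rep(-0.013, 5))$cl, 0.013)
  expect_error(confidence_limit_point(0.01), "two cases")
})

test_that("gamma confidence limits reproduce the frozen reference columns", {
  expect_equal(round_half_up(confidence_limit_gamma(c(99.1, 99.2, 99.7, 99.5))$cl, 1), 1.2)
  expect_equal(round_half_up(confidence_limit_gamma(c(99.7, 99.9, 98.5, 99.9))$cl, 1), 1.8)
  expect_equal(confidence_limit_gamma(rep(100, 4))$cl, 0)
  expect_error(confidence_limit_gamma(c(99, 102)), "\\[0, 100\\]")
})

test_that("aggregate_cl reproduces the abstract-style summaries", {
  a <- aggregate_cl(c(0.022, 0.024, 0.036, 0.029, 0.038))
  expect_equal(round_half_up(a$mean, 3), 0.030)
  expect_equal(round_half_up(a$sd, 3), 0.007)
  expect_equal(c(a$min, a$max), c(0.022, 0.038))
  expect_equal(round_half_up(aggregate_cl(c(0.043, 0.023, 0.016, 0.028, 0.035))$mean, 3),
               0.029)
  id <- aggregate_cl(rep(0.02, 3))
  expect_equal(id$sd, 0)
  expect_equal(id$min, id$max)
})

test_that("couch transmission differences match the reference table", {
  expect_equal(round_half_up(couch_transmission_diff(0.9767, 0.9682), 1), -0.9)
  expect_equal(couch_transmission_diff(0.98, 0.98), 0)
  couch <- qa_reference_table("couch")
  thin <- couch[couch$section == "thin", ]
  avg <- mean(couch_transmission_diff(thin$calculated, thin$measured))
  expect_equal(round_half_up(avg, 2), -0.50)
})

test_that("confidence limits are sign-symmetric and monotone in sigma", {
  set.seed(17)
  for (i in 1:10) {
    d <- stats::rnorm(8, 0.01, 0.01)
    expect_equal(confidence_limit_point(d)$cl, confidence_limit_point(-d)$cl)
  }
  base <- c(-1, -0.5, 0, 0.5, 1) / 100   # mean 0, unit shape
  cls <- vapply(seq(0.001, 0.02, length.out = 8), function(s)
    confidence_limit_point(base / stats::sd(base) * s + 0.005)$cl, 0)
  expect_true(all(diff(cls) > 0))
})

test_that("CL coverage on Normal case tables is at least 95%", {
  cover <- vapply(1:20, function(s) {
    tab <- gen_case_table(case_table_spec(n_cases = 1e5, bias = 0.002,
                                          sd = 0.015), seed = s)
    d <- dose_diff_ratio(tab$measured, tab$planned, tab$prescription)
    cl <- confidence_limit_point(d)$cl
    mean(abs(d) <= cl)
  }, 0)
  expect_true(all(cover >= 0.95))
})

test_that("build_report reproduces every printed per-energy CL within 0.001", {
  rep_ <- build_report(
    rbind(qa_reference_table("point_high"), qa_reference_table("point_low")),
    rbind(qa_reference_table("gamma_high"), qa_reference_table("gamma_low")),
    qa_reference_table("couch"))

  # printed point CLs by technique/energy/region
  printed <- rbind(
    data.frame(technique = "IMRT", region = "high",
               energy = c("6X", "10X", "15X", "6X-FFF", "10X-FFF"),
               cl = c(0.022, 0.024, 0.036, 0.029, 0.038)),
    data.frame(technique = "RapidArc", region = "high",
               energy = c("6X", "10X", "15X", "6X-FFF", "10X-FFF"),
               cl = c(0.043, 0.023, 0.016, 0.028, 0.035)),
    data.frame(technique = "IMRT", region = "low",
               energy = c("6X", "10X", "15X", "6X-FFF", "10X-FFF"),
               cl = c(0.029, 0.024, 0.027, 0.027, 0.039)),
    data.frame(technique = "RapidArc", region = "low",
               energy = c("6X", "10X", "15X", "6X-FFF", "10X-FFF"),
               cl = c(0.047, 0.022, 0.018, 0.031, 0.017)))
  got <- merge(rep_$point, printed,
               by = c("technique", "energy", "region"),
               suffixes = c("", "_printed"))
  expect_equal(nrow(got), 20)
  expect_true(all(abs(got$cl - got$cl_printed) <= 0.001 + 1e-12))

  # gamma CLs, low-dose plane: printed 1.2 / 1.8 anchors
  gl <- rep_$gamma[rep_$gamma$region == "low", ]
  expect_equal(round_half_up(
    gl$cl[gl$technique == "IMRT" & gl$energy == "6X"], 1), 1.2)
  expect_equal(round_half_up(
    gl$cl[gl$technique == "RapidArc" & gl$energy == "10X-FFF"], 1), 1.8)

  # abstract aggregates and baseline checks
  pa <- rep_$point_aggregate
  expect_equal(round_half_up(
    pa$cl_mean[pa$technique == "IMRT" & pa$region == "high"], 3), 0.030)
  expect_equal(round_half_up(
    pa$cl_mean[pa$technique == "RapidArc" & pa$region == "high"], 3), 0.029)
  expect_true(all(rep_$point$pass[rep_$point$technique == "IMRT"]))

  # couch averages
  ca <- rep_$couch_average
  expect_equal(round_half_up(ca$mean_diff_pct[ca$section == "thin"], 2), -0.50)

  expect_error(build_report(data.frame(), qa_reference_table("gamma_low")),
               "empty")
})

test_that("build_report CLs converge to |mu| + 1.96 sigma on synthetic tables", {
  tab <- gen_case_table(case_table_spec(n_cases = 4000, bias = 0.01,
                                        sd = 0.007), seed = 8)
  tab$technique <- "IMRT"; tab$energy <- "6X"; tab$region <- "high"
  rep_ <- build_report(tab, data.frame(case = 1:2, technique = "IMRT",
                                       energy = "6X", region = "high",
                                       rate = c(99, 100)))
  expect_equal(rep_$point$cl, 0.01 + 1.96 * 0.007, tolerance = 0.02)
})
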