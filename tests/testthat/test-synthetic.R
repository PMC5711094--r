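test_that("gen_beam_plane: flat FF interior, peaked FFF, seeded determinism", {
  ff <- gen_beam_plane(beam_model("FF", field_size = 60), spacing = 1)
  ax <- plane_axes(ff)
  interior <- ff$values[abs(ax$y) < 20, abs(ax$x) < 20]
  expect_lt(max(interior) - min(interior), 1e-12)

  fff <- gen_beam_plane(beam_model("FFF", field_size = 60, k = 0.004), spacing = 1)
  centre <- fff$values[ceiling(nrow(fff$values) / 2), ceiling(ncol(fff$values) / 2)]
  edge <- fff$values[ceiling(nrow(fff$values) / 2), which.min(abs(ax$x - 25))]
  expect_gt(centre, edge)
  # strictly decreasing radially inside the flat part of the field
  prof <- extract_profile(fff, "cross-plane", 0, 0)
  inside <- prof$positions >= 0 & prof$positions < 25
  expect_true(all(diff(prof$values[inside]) < 0))

  a <- gen_beam_plane(beam_model("FF"), noise_sd = 0.02, seed = 42)
  b <- gen_beam_plane(beam_model("FF"), noise_sd = 0.02, seed = 42)
  expect_identical(a$values, b$values)
  expect_false(identical(
    a$values, gen_beam_plane(beam_model("FF"), noise_sd = 0.02, seed = 43)$values))
})

test_that("FF forces k = 0 and invalid specs error", {
  expect_equal(beam_model("FF", k = 0.5)$k, 0)
  expect_error(beam_model("FFF", k = -1), "k must be")
  expect_error(beam_model("FF", penumbra = 0), "penumbra")
  expect_error(picket_fence_spec(gap = 1, spacing = 0.5), "exceed")
  expect_error(strip_pattern_spec(scales = c(1, -1)), "> 0")
})

test_that("gen_picket_fence returns exact truth including injected offsets", {
  beam <- beam_model("FF", field_size = 120)
  pf0 <- gen_picket_fence(picket_fence_spec(), beam)
  expect_equal(diff(pf0$truth), rep(15, 4))

  off <- c(0, 0, 0.5, 0, 0)
  pf <- gen_picket_fence(picket_fence_spec(offsets = off), beam)
  expect_equal(pf$truth - pf0$truth, off)

  expect_error(
    gen_picket_fence(picket_fence_spec(spacing = 1.2, n_pickets = 3,
                                       offsets = c(0, -0.5, 0)), beam),
    "overlap")
  s <- picket_fence_spec(noise_sd = 0.02)
  p1 <- gen_picket_fence(s, beam, seed = 7)
  p2 <- gen_picket_fence(s, beam, seed = 7)
  expect_identical(p1$plane$values, p2$plane$values)
})

test_that("detect_pickets on zero-noise fences recovers truth within 0.05 mm", {
  beam <- beam_model("FF", field_size = 120)
  pf <- gen_picket_fence(picket_fence_spec(offsets = c(0, 0.3, 0, -0.2, 0)),
                         beam)
  prof <- extract_profile(pf$plane, "cross-plane", 0, 10)
  peaks <- detect_pickets(prof, 5)
  expect_lt(max(abs(peaks - pf$truth)), 0.05)
})

test_that("gen_strip_pair construction matches its closed form", {
  beam <- beam_model("FF", field_size = 150)
  # all scales equal -> analyze_strips deviations ~ 0
  sp0 <- gen_strip_pair(strip_pattern_spec(), beam)
  res0 <- analyze_strips(sp0$strip, sp0$open, sp0$rois)
  expect_lt(max(abs(res0$table$diff_pct)), 1e-10)

  # injected scales reproduce the closed-form deviations exactly (noiseless)
  scales <- c(1.014, rep(1, 6))
  sp <- gen_strip_pair(strip_pattern_spec(scales = scales), beam)
  res <- analyze_strips(sp$strip, sp$open, sp$rois)
  expect_equal(res$table$diff_pct, (scales / mean(scales) - 1) * 100,
               tolerance = 1e-10)
  # hand arithmetic: mean scale (1.014 + 6)/7 = 1.002, so strip 1 deviates
  # by (1.014/1.002 - 1) = +1.1976% (the injected 1.4% damped by 6/7ths)
  expect_equal(res$table$diff_pct[1], (1.014 / 1.002 - 1) * 100,
               tolerance = 1e-9)

  s <- strip_pattern_spec(noise_sd = 0.01)
  a <- gen_strip_pair(s, beam, seed = 3)
  b <- gen_strip_pair(s, beam, seed = 3)
  expect_identical(a$strip$values, b$strip$values)
  expect_identical(a$open$values, b$open$values)
})

test_that("gen_film_scan inverts its truth curve exactly at zero noise", {
  fs <- gen_film_scan(seed = 1)   # noiseless despite seed
  od <- compute_od(fs$channels$R, fs$i0)
  ods <- vapply(fs$rois, function(r) roi_stats(od, r)$mean, 0)
  expect_equal(ods, fs$od_truth, tolerance = 1e-10)
  # dose-0 patch carries the curve's zero-dose intercept OD
  fs0 <- gen_film_scan(doses = c(0, 1, 2, 3))
  od0 <- compute_od(fs0$channels$R, fs0$i0)
  expect_equal(roi_stats(od0, fs0$rois[[1]])$mean,
               linacqa:::invert_calibration(fs0$curve, 0), tolerance = 1e-10)
  # channel sensitivity ordering R > G > B
  odg <- compute_od(fs$channels$G, fs$i0)
  expect_lt(roi_stats(odg, fs$rois[[9]])$mean,
            roi_stats(od, fs$rois[[9]])$mean)
})

test_that("gen_case_table realizes the stated bias/SD world", {
  # sigma = 0: every difference ratio equals the bias exactly
  t0 <- gen_case_table(case_table_spec(n_cases = 4, bias = 0.01, sd = 0))
  expect_equal(dose_diff_ratio(t0$measured, t0$planned, t0$prescription),
               rep(0.01, 4))
  # CLT: n = 5000 sample mean within 0.001 of mu
  tb <- gen_case_table(case_table_spec(n_cases = 5000, bias = 0.01, sd = 0.007),
                       seed = 99)
  d <- dose_diff_ratio(tb$measured, tb$planned, tb$prescription)
  expect_lt(abs(mean(d) - 0.01), 0.001)
  expect_identical(
    gen_case_table(case_table_spec(n_cases = 10), seed = 5),
    gen_case_table(case_table_spec(n_cases = 10), seed = 5))
})

test_that("gen_plane_pair scales then translates", {
  base <- ramp_plane(n = 30)
  same <- gen_plane_pair(base, 0, c(0, 0))
  expect_equal(same$evaluated$values, base$values)
  u <- uniform_plane(2, 12)
  err <- gen_plane_pair(u, 0.03, c(0, 0))
  expect_equal(err$evaluated$values, u$values * 1.03)
  sh <- gen_plane_pair(base, 0, c(3, 0))
  ax <- plane_axes(base)
  inner <- which(ax$x > min(ax$x) + 4 & ax$x < max(ax$x))
  slope <- (2.5 - 0.5) / (30 - 1)
  expect_equal(sh$evaluated$values[15, inner],
               base$values[15, inner] - 3 * slope, tolerance = 1e-10)
})
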