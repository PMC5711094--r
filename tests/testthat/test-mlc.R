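test_that("detect_pickets refines sub-pixel positions and counts peaks", {
  # triangular peak with apex between samples: parabolic refinement within
  # 0.1 px of the true apex
  x <- seq(-10, 10, by = 1)
  x0 <- 0.3
  tri <- pmax(0, 1 - 0.2 * abs(x - x0))
  pk <- detect_pickets(qa_profile(x, tri), 1)
  expect_lt(abs(pk - x0), 0.1)

  expect_error(detect_pickets(qa_profile(x, rep(2, length(x))), 1), "uniform")
  # wrong expectation reports the found count
  two <- exp(-(x + 4)^2) + exp(-(x - 4)^2)
  expect_error(detect_pickets(qa_profile(x, two), 3), "found 2")
})

test_that("fwhm matches closed forms", {
  xr <- seq(-20, 20, by = 0.5)
  rect <- ifelse(abs(xr) <= 3, 1, 0)   # width-6 pulse
  expect_lt(abs(fwhm(qa_profile(xr, rect), 0) - 6), 0.5 + 1e-9)

  xf <- seq(-20, 20, by = 0.02)
  sig <- 2.5
  gauss <- exp(-xf^2 / (2 * sig^2))
  expect_equal(fwhm(qa_profile(xf, gauss), 0, window_mm = 20),
               2 * sqrt(2 * log(2)) * sig, tolerance = 0.01)
  # sloped FFF-like background: the local-window minimum keeps the FWHM in
  # the right ballpark where a global zero background would not
  gslope <- gauss + 0.2 + 0.005 * xf
  expect_equal(fwhm(qa_profile(xf, gslope), 0, window_mm = 10),
               2 * sqrt(2 * log(2)) * sig, tolerance = 0.1)
  expect_error(fwhm(qa_profile(xr, 1 + 0.001 * xr), 0), "cross half maximum")
})

test_that("fwhm is unbiased on noisy pickets (Monte Carlo)", {
  beam <- beam_model("FF", field_size = 40)
  spec0 <- picket_fence_spec(n_pickets = 1, spacing = 10, blur_sigma = 1)
  ref <- gen_picket_fence(spec0, beam)
  prof0 <- extract_profile(ref$plane, "cross-plane", 0, 5)
  w0 <- fwhm(prof0, 0)
  spec <- picket_fence_spec(n_pickets = 1, spacing = 10, blur_sigma = 1,
                            noise_sd = 0.02)
  ws <- vapply(1:100, function(s) {
    pf <- gen_picket_fence(spec, beam, seed = s)
    fwhm(extract_profile(pf$plane, "cross-plane", 0, 5), 0)
  }, 0)
  expect_lt(abs(mean(ws) - w0) / w0, 0.05)
})

test_that("compare_pickets applies tolerance and reporting thresholds", {
  ref <- c(-30, -15, 0, 15, 30)
  r0 <- compare_pickets(ref, ref)
  expect_true(r0$pass)
  expect_equal(r0$deviation, rep(0, 5))
  expect_false(any(r0$flagged))

  r1 <- compare_pickets(ref + c(0, 0, 0.5, 0, 0), ref)
  expect_true(r1$pass)                       # within the 1 mm tolerance
  expect_identical(which(r1$flagged), 3L)    # but surfaced above 0.25 mm
  r2 <- compare_pickets(ref + c(0, 0, 1.5, 0, 0), ref)
  expect_false(r2$pass)
  expect_error(compare_pickets(c(1, 0, 2), c(0, 1, 2)), "increasing")
})

test_that("an injected 0.5 mm picket error is recovered within 0.1 mm", {
  beam <- beam_model("FF", field_size = 120)
  ref <- gen_picket_fence(picket_fence_spec(), beam)
  tst <- gen_picket_fence(picket_fence_spec(offsets = c(0, 0, 0.5, 0, 0)),
                          beam)
  find <- function(pf) detect_pickets(
    extract_profile(pf$plane, "cross-plane", 0, 10), 5)
  rep_ <- compare_pickets(find(tst), find(ref))
  expect_equal(rep_$deviation[3], 0.5, tolerance = 0.1)
  expect_lt(max(abs(rep_$deviation[-3])), 0.1)
  expect_true(rep_$pass)
  expect_identical(which(rep_$flagged), 3L)
})

test_that("rcorr reproduces the reference readings and is scale-invariant", {
  # frozen reference values: strip/open pairs print as 108.31 and 55.68
  expect_equal(round_half_up(rcorr(74.06, 68.38), 2), 108.31)
  expect_equal(round_half_up(rcorr(37.37, 67.12), 2), 55.68)
  expect_equal(rcorr(51.3, 51.3), 100)
  for (c_ in c(0.5, 3, 1000))
    expect_equal(rcorr(74.06 * c_, 68.38 * c_), rcorr(74.06, 68.38))
  expect_error(rcorr(50, 0), "> 0")
})

test_that("strip_deviations reproduces the reference table rows", {
  # seven-strip DR/GS row: diffs round to the printed values, mean 0.43%
  r6 <- c(108.31, 107.01, 106.74, 106.54, 106.39, 106.47, 106.55)
  d6 <- strip_deviations(r6)
  expect_equal(round_half_up(d6$diff_pct, 1),
               c(1.4, 0.1, -0.1, -0.3, -0.4, -0.4, -0.3))
  expect_equal(round_half_up(d6$mean_abs_pct, 2), 0.43)
  expect_true(all(d6$pass))
  # four-strip LS/DR FFF row: mean |dev| 0.25%
  r4 <- c(104.41, 104.78, 104.97, 104.31)
  expect_equal(round_half_up(strip_deviations(r4)$mean_abs_pct, 2), 0.25)
  # equal readings -> all zero
  expect_equal(strip_deviations(rep(97.5, 5))$diff_pct, rep(0, 5))
})

test_that("equal-weight deviations sum to zero (algebraic identity)", {
  set.seed(31)
  for (i in 1:20) {
    r <- stats::runif(sample(3:9, 1), 50, 150)
    expect_equal(sum(strip_deviations(r)$diff_pct), 0, tolerance = 1e-10)
  }
})

test_that("analyze_strips validates geometry and disjoint ROIs", {
  beam <- beam_model("FF", field_size = 150)
  sp <- gen_strip_pair(strip_pattern_spec(), beam)
  other <- gen_strip_pair(strip_pattern_spec(), beam, spacing = 2)
  expect_error(analyze_strips(sp$strip, other$open, sp$rois), "share")
  overlapping <- list(qa_roi(-10, 5, -10, 10), qa_roi(0, 10, -10, 10))
  expect_error(analyze_strips(sp$strip, sp$open, overlapping), "overlap")
})

test_that("picket position error shrinks as blur and noise shrink", {
  beam <- beam_model("FF", field_size = 120)
  err_at <- function(noise) {
    mean(vapply(1:5, function(s) {
      pf <- gen_picket_fence(picket_fence_spec(noise_sd = noise), beam,
                             seed = s)
      pk <- detect_pickets(extract_profile(pf$plane, "cross-plane", 0, 10), 5)
      max(abs(pk - pf$truth))
    }, 0))
  }
  errs <- vapply(c(0.05, 0.01, 0), err_at, 0)
  expect_lte(errs[3], errs[2] + 1e-9)
  expect_lte(errs[2], errs[1] + 1e-9)
  expect_lt(errs[3], 0.05)
})
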