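---
title: "linacqa: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{linacqa: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: what each
analysis computes, which assumptions and defaults it rests on, what the
synthetic-data generators do and do not emulate, and where the design was
genuinely open. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## 1. The problem

Before IMRT or VMAT treatments go clinical on a new linac, the delivery
chain is verified end to end: MLC leaf positioning (picket-fence tests),
the machine's joint control of dose rate, gantry speed and leaf speed
during arc delivery (strip tests), planar dose agreement between
measurement and calculation (film dosimetry + gamma analysis), and
point-dose agreement summarized as TG-119 confidence limits that become
the action levels for routine patient-specific QA. `linacqa` implements
the analysis side of that battery. It does not talk to a linac, a TPS or a
scanner: inputs arrive as 2D planes (CSV grid, single-frame DICOM RT Dose,
or 48-bit RGB TIFF film scans) and per-case tables (CSV).

## 2. Dose planes and geometry

All planar data are carried as a `dose_plane`: a matrix plus pixel spacing
(mm), the physical coordinate of the first sample, and a quantity tag
(`dose`, `reading`, `od`, `gamma`). Conventions, chosen once and used
everywhere:

* physical coordinates in mm; pixel **centres** are addressed;
* rows run along the in-plane (y) axis, columns along the cross-plane (x)
  axis; synthetic planes put the origin at the grid centre;
* ROIs are rectangles in mm, **half-open** on their max edges, so
  adjacent strip ROIs partition pixels without double counting;
* every SD in the package is the sample SD (n−1) — the convention under
  which the bundled reference confidence limits reproduce exactly;
* printed-table comparisons round half away from zero
  (`round_half_up()`), because that is how the reference tables round.

The `csv-grid` dialect (two header lines — spacing and quantity, then
origin — followed by comma-separated rows, written with 17 significant
digits) round-trips bit-exactly; that is asserted in the tests. DICOM
support is deliberately narrow: single-frame RT Dose, explicit VR little
endian, with Dose Grid Scaling applied and the Grid Frame Offset Vector
ignored; missing geometry metadata is an error, never a silent default.
No R DICOM or TIFF reader was available in the deployment environment, so
minimal readers are implemented in-package; the TIFF path is
cross-validated against an independent Python reader in the test suite.

## 3. The synthetic world

The generators state a world once and return its ground truth alongside
the data; tests never re-derive truth from a generated image.

* **Beam model.** A square field with a linear-ramp penumbra of half-width
  3 mm. The ramp (rather than an error-function penumbra) makes the FF
  interior *exactly* flat, which lets flatness tests assert equality at
  1e-12 instead of hiding a 1e-7 ripple. FFF mode multiplies the envelope
  by `1 − k·r` clipped at zero; the default `k = 0.003`/mm puts the value
  100 mm off-axis at ~70% of the central axis, qualitatively matching the
  forward-peaked shape of an unflattened beam. Only monotonicity is ever
  asserted about this shape — it is a stand-in, not a beam model fit.
* **Picket fence.** Transmitted slits of width 1.0 mm (the clinical
  pattern) spaced 15 mm apart over a 2% leakage floor, blurred with a
  Gaussian of σ = 1 mm (source size plus detector blur), sampled at
  0.25 mm (EPID-like). Per-picket offsets inject leaf errors with exact
  truth. Noise is multiplicative Gaussian on readings.
* **Strip patterns.** 7 strips × 18 mm for DR_GS, 4 strips for LS_DR; the
  strip plane is the open plane times a per-strip scale factor, so the
  open-field correction cancels the beam profile identically in the
  noiseless case and the injected scales are the exact expected
  deviations.
* **Film scans.** A 3×3 grid of 2×2 cm patches spanning 0.4–3.2 Gy at
  75 dpi. Patch OD is obtained by inverting the true calibration curve at
  the nominal dose; the channel reading is `i0·10^−OD` with `i0 = 60000`
  (a transmission scan of unexposed film stays safely below 16-bit
  saturation). Green and blue carry the red-channel OD scaled by 0.75 and
  0.5, emulating their lower dose sensitivity. "1% OD noise" means
  additive Gaussian noise with SD equal to 1% of the local OD. Channels
  are kept unquantized in memory; 16-bit rounding happens only on TIFF
  export, so noiseless calibration recovery is exact by construction.
* **Case tables.** Per-case dose-difference ratios are Normal(bias, SD)
  by construction — the TG-119 decomposition into systematic and random
  components. Defaults (bias −0.002, SD 0.015 of a 2 Gy prescription)
  describe a well-commissioned machine.

What the generators do **not** emulate: detector lag and ghosting, EPID
saturation under FFF dose rates, film lateral-response and curl artifacts,
scanner warm-up drift, couch/MLC physics, or any delivery dynamics (the
DR/GS control-point schedule is treated as annotation, not simulated). A
green test therefore establishes that the *analysis* is correct on data
with known truth — not that a real machine passes.

## 4. MLC analyses

**Peak finding.** Picket peaks are local maxima above a prominence
threshold (30% of the profile range above its minimum), refined to
sub-pixel accuracy by a 3-point parabola fitted to the *logarithm* of the
samples — exact for Gaussian-shaped peaks, and within 0.1 px for
triangular ones (asserted against the closed form). A plain parabola is
the fallback when a neighbour is non-positive. Finding more or fewer
prominent peaks than expected is an error that reports the found count.

**FWHM.** The background is the profile minimum inside a local window
around the peak rather than a global zero, because FFF film profiles ride
on a sloped beam background; crossings are located by linear interpolation
walking outward from the peak.

**Tolerance logic.** `compare_pickets()` passes when max |deviation| ≤
1.0 mm (the clinical criterion) and *additionally* flags any picket above
a 0.25 mm reporting threshold, so a deliberate 0.5 mm error is surfaced
even though it passes — mirroring how sub-millimetre intentional errors
are expected to be "easily discerned" while remaining inside tolerance.

**Strip tests.** Strip ROIs default to the central 60% of each strip
(penumbra clearance; no published margin exists, so one was fixed here),
per-strip pass tolerance defaults to 2% (a 1.4% deviation is known-good;
no explicit limit is published; configurable). The per-strip deviations
sum to zero by construction — an algebraic identity the tests exercise.

## 5. Film dosimetry

OD is `log10(i0/pixel)` with a per-scan reference `i0` (e.g. an unexposed
region), removing lamp drift to first order; saturated pixels are flagged
in a mask. Calibration fits **dose as a cubic polynomial of OD** by least
squares — the direction matches how the curve is used, at the price of
non-uniform dose spacing. The fit records its rms residual and a
numerical monotonicity check over the fitted OD span; a non-monotone fit
warns rather than failing, since the curve may still be monotone over the
clinically used sub-range. The red channel is the default analysis
channel (highest sensitivity below ~4 Gy); fitting one channel never
reads another. Registration is exhaustive NCC over translation (±10 mm)
and rotation (±5°) with a separable sub-grid refinement — deterministic,
with a degenerate-registration error on flat correlation surfaces.
Post-irradiation wait time and scanner warm-up are protocol metadata, not
modelled. Multi-channel simultaneous optimization and lateral scanner
corrections are out of scope.

## 6. Gamma analysis

The engine minimizes the combined dose/distance metric over candidate
shifts on a disc of radius 3·dta, sampling the evaluated plane bilinearly.
Numerical choices that matter:

* **Normalization** defaults to global (the reference maximum), the
  TG-119-era clinical convention; local normalization is available and
  reported in the output.
* **Low-dose threshold** defaults to 10% of the reference maximum; there
  is no universal value, so it is configurable and always reported.
* **Step size** defaults to dta/20. The discretization error of the
  distance term scales with the step; dta/10 was measured to produce
  disagreements up to ~0.25 in γ against a dta/20 exhaustive search,
  while at dta/20 the optimized engine agrees with the brute-force oracle
  to machine precision (the suite asserts ≤ 0.02 on ≥ 99% of pixels over
  20 seeded plane pairs).
* **Early termination**: candidates are visited in order of increasing
  distance and the search stops once the distance term alone exceeds the
  worst current γ — an exact optimization, not an approximation.
* **Tie-break at the criterion**: a dose error exactly at tolerance gives
  γ = 1 only up to floating point, so the passing test is γ ≤ 1 + 1e-9.
* A uniform plane with a uniform 3% error at 3% tolerance gives γ = 1
  everywhere (the DTA term cannot help on a uniform field). A linear
  gradient of slope *s* shifted by exactly dta does **not** give γ = 1:
  the quadratic trade-off admits the closed form
  γ = (shift/dta)·t/√(1+t²) with t = dta·s/δD, ≈ 0.85 for a full-range
  ramp across a 50 mm grid. The tests assert the engine against this
  closed form rather than the γ = 1 folklore.

Gamma is not symmetric under swapping reference and evaluated planes;
that asymmetry is expected and not asserted against.

## 7. TG-119 statistics

Point-dose differences are `(measured − planned)/prescription`; CLs are
|mean| + 1.96·SD (point) and 100 − mean + 1.96·SD (gamma passing rates),
with sample SD. Differences are carried as fractions internally and
printed as % where the reference tables do. Reproduction tests allow ±1
unit in the last printed digit, because the reference per-case entries
are themselves rounded to 0.1% and that input rounding propagates ~0.001
into a recomputed CL. Baseline action levels default to the
multi-institution TG-119 averages (0.045 high-dose, 0.047 low-dose);
`build_report()` evaluates point CLs against them and aggregates CLs over
energies (mean, sample SD, range). The bundled high-dose gamma table's
per-case entries are used as-is; its printed summary rows are not
recomputable from them for several columns in the source material, so
only the low-dose gamma columns anchor the acceptance targets. Coverage
of the point CL is ≥ 95% for Normal differences by construction (the
interval [−|μ|−1.96σ, |μ|+1.96σ] contains [μ−1.96σ, μ+1.96σ]); the suite
verifies this on simulated case tables at n = 1e5.

## 8. Known limitations

* 2D only: no 3D gamma, no multi-frame RT Dose volumes.
* No per-leaf attribution of picket errors, no trajectory-log analysis.
* Film model omits lateral scanner response and triple-channel
  simultaneous dose mapping; the often-quoted ~2% overall film
  uncertainty is a reporting constant here, not a propagated error model.
* The couch analysis consumes transmission factors; it does not model
  couch HU values or TPS structures.
* Registration assumes rigid motion within ±10 mm / ±5° and a non-flat
  dose distribution; it will (correctly) refuse uniform images.
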