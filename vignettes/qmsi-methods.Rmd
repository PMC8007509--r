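---
title: "Methods: mimetic-array calibration and regional quantification in qmsi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mimetic-array calibration and regional quantification in qmsi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmsi)
```

## The quantification problem

Targeted MSI acquires, per pixel, one integrated intensity per MRM
transition. Absolute quantification of a drug in tissue from such images
faces two obstacles: tissue ion suppression (the matrix attenuates the
analyte signal in a region-dependent way) and the absence of an
isotope-labelled internal standard for compounds early in development.
`qmsi` implements the mimetic-tissue-model answer: calibrate against wells
of drug-spiked tissue homogenate embedded in gelatin and sectioned alongside
the sample, and normalize every analyte channel to a homogeneously
distributed endogenous lipid channel acquired in the same run.

All statistics operate on the **summed ratio** of an ROI,
`r(P) = Σ I_drug / Σ I_lipid`. Summing before ratioing (rather than
averaging per-pixel ratios) keeps low-count pixels from dominating and makes
the statistic invariant to pixel order; it is also the natural estimator
when both channels are Poisson-like counts.

## Calibration, LOD/LLOQ, exclusion

`fit_line()` regresses the per-level mean ratio on nominal concentration by
**ordinary unweighted least squares with a free intercept**. Weighted
regression is a reasonable alternative for heteroscedastic ratio noise, but
for this class of data it has been evaluated and found not to improve
linearity, so the package deliberately offers only the unweighted fit; the
coefficient of determination is computed on the per-level means actually
fitted (and defined as 0 when the response is constant).

Detection limits derive from blank variability on the ratio scale:
`LOD = 3·SD_blank/slope`, `LLOQ = 5·SD_blank/slope`. `SD_blank` is the
*sample* (n−1) standard deviation of the blank replicate summed ratios —
replicate ROIs/wells, not per-pixel ratios — matching the triplicate-blank
design and small-n bioanalytical convention. Consequently `LLOQ/LOD = 5/3`
identically, which the tests assert.

`build_calibration()` applies the below-LOD exclusion rule iteratively: fit,
compute LOD, drop calibration levels with nominal < LOD, refit, repeat until
the included set is stable. A single-pass reading of the rule is also
defensible; the fixpoint was chosen because it makes the procedure
idempotent (re-running it on its own output changes nothing), which is both
testable and the only variant under which the reported LOD is consistent
with the curve that produced it. If exclusion would leave fewer than three
levels, calibration fails loudly, reporting the last LOD. The ULOQ is the
highest included level.

QC wells at 25 and 1250 µg/g are judged by the characterization criteria
used for chromatographic toxicology assays: precision ≤ 15 %RSD (relaxed to
20 % when the nominal is at or below the LLOQ) and accuracy within −20 % to
+10 % of nominal, encoded as 80–110 %. The accuracy window is asymmetric by
design; `qc_criteria()` makes all four bounds configurable.

## Cell-density correction

The endogenous lipid scales with intact-cell density, and homogenization
disrupts cells, so the calibrants sit at a lower intact-cell density than
dense tissue regions. Ratios measured on tissue are therefore rescaled by
`calibration_density / mean ROI density` before back-calculation
(`cell_corrected_ratio()`). No published arithmetic exists for this
correction; this multiplicative form is the package's own declared choice,
isolated behind a single function, and the synthetic generator encodes the
matching generative model (analyte expectation ∝ concentration ×
density²/calibration density, lipid ∝ density) so that the correction is
exact by construction on synthetic data. On real data its validity rests on
the lipid-density proportionality assumption; if that fails regionally, the
correction inherits the error.

## What the synthetic generator emulates — and what it does not

`generate_mimetic_array()` reproduces the physical array: a 20 × 20 mm
gelatin block, 4 × 4 pillar positions minus one empty orientation corner,
3 × 3 mm square wells with 2 mm corridors, rasterized at `pixel_size_um`
(default 100 µm → 30 × 30 px = 900 px/well). The default fill is the 8-level
ladder 12.5, 25, 50, 125, 250, 500, 1250, 2500 µg/g, triplicate blanks and
duplicate wells per QC level (25, 1250 µg/g) — 15 wells, with well contents
assigned to positions in seeded random order to mimic the randomized fill of
the physical block. Replicate homogenate preparations are modelled as
replicate sections (`simulate_calibration_experiment(n_sections = 3)`), each
with independent noise; within one section only 15 positions exist, which is
why QC levels appear in duplicate rather than triplicate there.

Noise is multiplicative log-normal per pixel with mean exactly 1 and
relative SD `pixel_rsd` (default 0.2, the ~20 % pixel-to-pixel RSD observed
for the lipid channel in liver homogenates), plus additive Gaussian baseline
noise (`baseline_noise_sd`, default 5 counts) truncated at zero so
intensities stay non-negative. Analyte channels are parameterized **on the
ratio scale**: `response_slope` (ratio units per µg/g, default 0.002) fixes
the expected summed ratio of a well, so ion suppression is implicitly shared
between channels and absolute counts are arbitrary units — no absolute
intensity scale is claimed. Inter-well diffusion, when enabled, is a
Gaussian blur (`diffusion_sigma_mm`) of the expected intensity fields with
zero-padding at the image edge.

The generator does **not** simulate mass spectra, peak shapes, m/z axes,
ion-mobility behaviour, cryosectioning artifacts, or histology images:
channels are already-integrated MRM intensities and cell densities arrive as
maps. Passing tests therefore validate the statistical pipeline — not
instrument physics. In particular, real blank variability (and hence real
LODs in the tens-to-hundreds of µg/g for insensitive modes) is dominated by
chemical background the generator does not model; synthetic LODs are small.

Key generator defaults, chosen once as realistic study conditions:

| parameter | default | units | rationale |
|---|---|---|---|
| `response_slope` | 0.002 | ratio per µg/g | ratio ≈ 5 at the 2500 µg/g top level |
| `lipid_gain` | 20 | counts per cell | lipid ≈ 1000 counts/px at calibration density |
| `pixel_rsd` | 0.2 | fraction | observed pixel RSD of the lipid channel |
| `baseline_noise_sd` | 5 | counts | small additive noise floor |
| `homogenate_cell_density` | 50 | cells/px | calibration density the correction refers to |
| `diffusion_sigma_mm` | 0 | mm | corridors are clean unless probed |
| `pixel_size_um` | 100 | µm | multiplatform acquisition pixel size |

## Numerical and design choices

* **Geometry** uses 0-based, half-open pixel rectangles
  `[x0, x0+w) × [y0, y0+h)`; (0,0) is the top-left pixel, x grows rightward,
  y downward. Registration (`register_and_extract()`) maps ROI pixels
  through an affine transform and rounds to the nearest pixel without
  interpolating intensities — MRM counts are per-pixel integrals and
  interpolation would fabricate signal.
* **Determinism**: every generator consumes an explicit integer seed and a
  fixed seed reproduces grids bit for bit; pipeline outputs embed the seed
  and the config hash, so reruns are byte-identical.
* **Diffusion check**: the contamination fraction compares corridor pixels
  (≥ margin from every well, default 3 px) against a far background outside
  the well bounding box. The background is only a clean reference when the
  imaged area extends beyond the block by more than the diffusion length;
  the packaged checks therefore image a 4 mm margin when probing σ up to
  1 mm. The fraction is clipped at zero.
* **Flags**: back-calculation flags `below_lod < below_lloq < ok <
  above_uloq`; regions with any replicate above the ULOQ report `>ULOQ`
  with no concentration (extrapolating above the highest calibrant is not
  defensible), and analyte channels with no curve or no signal report `ND`.
* **Mode ranking** (`rank_modes()`): the field argues "best mode" in prose;
  the packaged ordering — criteria passed, then lower LOD, then higher R² —
  is an explicit, configurable convention, with ties kept in input order and
  logged.
* **Problem sizes in the packaged checks**: the statistical acceptance
  properties run 200 seeded experiments at the default 900 px/well geometry
  (parameter recovery) and 200 seeded round trips on a 120 × 120 px section
  with a 200 µm-raster calibration array — sizes at which the Monte-Carlo
  rates are stable to a percent or two and the whole suite runs in about a
  minute. At much coarser rasters (≈ 200 px/well) the unweighted-OLS
  intercept noise makes low-QC accuracy noticeably more variable; that is a
  property of the unweighted fit at the low end of a 200-fold ladder, worth
  knowing when designing real arrays.

## Known limitations

* The cell-density correction formula is an assumption, not a measurement;
  see above.
* Unweighted OLS with a free intercept determines low-end concentrations
  (near the 12.5–25 µg/g levels) less precisely than the high end; the
  low-QC accuracy is the first statistic to suffer when per-well pixel
  counts are small.
* LC-MS concordance uses the nearest bound of a range-valued reference, a
  conservative convention: a value inside the range scores exactly 1.
* The imzML importer handles continuous and processed files with 32/64-bit
  float or integer arrays and external `.ibd` storage; vendor raw formats
  and writing imzML are out of scope.
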