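---
title: "PunctaCycle: models, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PunctaCycle: models, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

PunctaCycle quantifies punctate cytoplasmic ribonucleoprotein granules
(processing bodies, PBs) in 8-bit multi-channel micrographs and tests
their per-field statistics for circadian rhythmicity. This vignette
records the models behind each stage, the parameters that matter, the
numerical conventions, and the choices made where the design was
genuinely open.

## The detection model

A PB is modeled as a diffraction-limited, near-circular focus a few
hundred nanometers across, sitting on a slowly varying cytoplasmic
background. The chain `detectFoci()` runs is:

1. **Gaussian blur**, σ = 0.8 px. Suppresses single-pixel noise while
   widening a ~2 px-σ spot only marginally. Implemented as separable
   convolution with a kernel truncated at 4σ and mirror-reflected
   borders; σ = 0 is the identity.
2. **Rolling-ball background subtraction**, radius 5 px. The
   background is the grayscale opening of the image by a ball
   (spherical-cap) structuring element — the upper envelope of a ball
   rolled beneath the intensity surface. Any structure narrower than
   the ball (the foci) cannot support the ball and is excluded from
   the background, so subtraction preserves spike height while
   flattening ramps and plateaus. The opening is computed exactly
   (erosion then dilation with the rasterized ball, out-of-image
   offsets padded ±∞); no shrink/interpolate speed-ups are used, which
   keeps the operation testable against a brute-force oracle.
3. **Fixed threshold**, inclusive lower bound, 40 (red) / 35 (green)
   on the 8-bit scale. The threshold is a per-experiment constant and
   is never adapted per image: automatic thresholding would respond to
   the very intensity changes the time course is meant to measure.
4. **Particle analysis**: connected components under 8-connectivity,
   then a filter keeping area 3–300 px² and circularity
   4π·area/perimeter² in [0.7, 1].

Mean particle intensity is measured on the blurred,
background-subtracted floating-point image (the raw-image mean is kept
for diagnostics); all processing is floating point, with quantization
only at file output.

### Pixel-size calibration

The single physical calibration constant is the pixel size,
102.33 nm/px. It is chosen so that the area filter maps onto round
physical diameters: d = p·2√(A/π) gives 200 nm at 3 px² and 2000 nm
at 300 px². It is configurable everywhere (`pixelSizeNm`).

### Numerical conventions

* Threshold inclusive at the lower bound; upper bound 255.
* 8-connectivity for labeling (diagonal neighbours connect), the
  particle-analysis default of the common desktop tools.
* Perimeter by Moore-neighbour outer-contour tracing with Jacob's
  stopping criterion; axial steps count 1, diagonal steps √2. A
  digital disk of radius 10 px then scores circularity ≈ 0.9; a 1-px
  line scores ≈ 0.17. Single-pixel regions are defined as circularity
  1 and interior holes are neither filled nor traced.
* Circularity is capped at 1 (tiny regions can exceed it on any
  discrete perimeter estimator).

### Known bias

Thresholding a Gaussian spot keeps only the pixels above the cut, so
the detected area underestimates the nominal cross-section; with the
default brightness (peak ≈ 85 counts over background) the mean
detected equivalent diameter runs 10–15% below the nominal spot
diameter. The acceptance checks budget for exactly this bias. It is a
property of the measurement procedure (also present in the original
desktop workflow), not of the simulation.

## Per-field metrics

The statistical replicate is the field (micrograph), not the particle:
per-field means of intensity and area, the per-field count, and the
per-field nuclei count feed the statistics. Counts are normalized by
the cell-covered area fraction (`normalizeCount`), i.e. reported as
count-per-fully-covered-field, because fields are rarely fully covered
by cells. The cell mask is a low-threshold segmentation of the diffuse
cytoplasmic signal: max-projection of the non-DAPI channels, blur
(σ = 2 px), fixed threshold 8/255, morphological closing (7 px disc)
and hole filling. The threshold is deliberately a configurable
constant — the original workflow only names the tool used, so the
simplest reproducible rule was chosen.

Nuclei are counted in the DAPI channel by blur → Otsu → hole fill →
label → reject components under 2000 px² (≈ 4.6 µm diameter). Touching
nuclei are not split (no watershed): counts, not shapes, are needed,
and the documented cost is a mild undercount when nuclei clump or are
clipped by the field edge.

Colocalization intersects the two channels' particle masks pixelwise
and relabels the intersection, keeping the ≥ 3 px² size floor but *not*
the circularity filter — the intersection of two circular foci imaged
through different antibodies need not be circular, and reporting the
intersection's own (smaller) areas is what reproduces the reduced
colocalized areas seen in double-labeling experiments.

## Rhythm statistics

Kruskal–Wallis (tie-corrected, χ² on k−1 df) with Dunn's
multiple-comparison test (shared ranking, tie-corrected variance,
Bonferroni by default, Holm by flag) compares timepoints on per-field
values. Rhythm detection runs on the per-timepoint mean series by
default — one value per timepoint, the natural unit of a
published-table reanalysis; `mode = "fields"` feeds the per-field
replicates to the two methods that tolerate uneven sampling.

Three detectors scan the circadian band (default 20–28 h):

* **Lomb–Scargle**: variance-normalized periodogram on a dense period
  grid (0.05 h step); the single-frequency null is the exact beta tail
  (1 − 2z/(n−1))^((n−3)/2) for Gaussian noise.
* **Rank concordance (JTK-style)**: Kendall's τ against reference
  cosines with lattice periods (multiples of the sampling step inside
  the band) and phases at sampling resolution; tie-corrected normal
  approximation for the null of S with continuity correction.
* **Autoregressive harmonic regression (ARSER-style)**: linear
  detrend, Savitzky–Golay smoothing (cubic, window 5), candidate
  periods from interior peaks of the AR spectral density (Yule–Walker
  and Burg fits; the ML variant is omitted — on short detrended series
  its optimizer is fragile and an order of magnitude slower), harmonic
  regression at each candidate, best model by AIC, F-test against the
  flat model. With no interior spectral peak the best-fitting period
  in the band is used. Requires regular sampling; gaps up to 20% of
  the design grid are linearly interpolated, beyond that the method is
  skipped (as is the concordance scan).

### Calibration of the p-values

Each method reports the *best* candidate in the band, so its raw
single-test p is anticonservative; conversely a Bonferroni over the
full reference grid of the concordance scan is strongly conservative,
because phase-shifted cosines of one period span only a 2-dimensional
space. Rather than hand-pick correction factors, the package
calibrates empirically: `rhythmCalibration()` simulates the joint null
of the three raw p-values on the observed sampling grid (800 seeded
white-noise draws, fixed internal RNG stream, caller's RNG state
untouched, cached per grid) and summarizes each method's selection
effect as an effective number of independent tests M, anchored at the
5th null percentile: p_corrected = 1 − (1 − p_raw)^M. On the default
16-point grid the measured type-I error at α = 0.05 is ≈ 0.065 / 0.048
/ 0.051 for LS / JTK / ARS; the analytic signal path is untouched, so
strong signals still yield arbitrarily small p.

### Integration

The consensus record takes the arithmetic mean of the method periods,
the circular mean of the phases (each mapped to an angle through its
own period), and a cosinor amplitude at the integrated period. For the
combined p, Fisher's method assumes independent tests, but the three
detectors run on the same series and their −2 log p are strongly
correlated (null covariances ≈ 3.5–4.4 vs 0 under independence);
plain Fisher then rejects a true null about 11% of the time at
α = 0.05. `metaIntegrate()` therefore uses Brown's method — Fisher's
generalization to correlated tests, with the covariance estimated by
the same grid calibration — which restores ≈ 5% (measured 0.051).
Without a calibration object it reduces to plain Fisher, which is also
the single-method and closed-form behavior. A single available method
is returned unchanged.

Reanalyzing the published per-timepoint mean PB-count series (both
markers, 16 points, 8–68 h) with this integration yields periods of
23.75 h and 23.34 h against the reported 23.57 h and 23.33 h; the
residual 0.2 h discrepancy for the first marker comes from the
declared approximation to the original meta-analysis tool's internal
period grids, which this package does not reproduce bug-for-bug.

### Cosinor conventions

`cosinorFit()` solves y = M + β₁cos(ωt) + β₂sin(ωt) in closed form;
A = √(β₁² + β₂²), acrophase φ = atan2(β₂, β₁)/ω mapped to [0, T). When
A is numerically zero the acrophase is undefined and reported missing.

## The synthetic-field generator

The generator emulates the study conditions of a
dexamethasone-synchronized neuroblastoma time course, and its defaults
*are* those conditions: 1376 × 1038 px 8-bit fields at 102.33 nm/px;
16 timepoints from 8 to 68 h every 4 h; 20 fields per timepoint;
23.6 ± 9.1 nuclei per field; spot diameters 476 ± 60 nm (the mean
detected diameter reported for PBs, used as the nominal spot FWHM).
Where the study reports no value, defaults were fixed once at
field-realistic levels and justified here:

* **Count program** mesor 240, amplitude 55, period 24 h, acrophase
  6.5 h — normalized counts and a ~23% relative amplitude in the
  middle of the published per-timepoint range, with the acrophase near
  the plausible reading of the published phase entry.
* **Spot brightness** (peak over background) mesor 85, amplitude 5.
  This puts the *measured* mean particle intensity at ≈ 52 a.u. on the
  background-subtracted image, inside the published 40–60 a.u. band,
  with the few-percent relative amplitude the published intensity
  rhythms show.
* **Area program** mesor 17 px², amplitude 1 px². The program scales
  spot diameters by √(value/mesor), so the mesor reproduces the
  nominal 476 nm and the published ~5% relative area amplitude is
  respected. Detected areas then fall in the published 10–18 px²
  range.
* **Colocalized fraction** 0.6, defined per channel: each channel
  carries one program-driven count N, of which ρN spots are rendered
  at identical centers in both channels and (1−ρ)N are
  channel-private. This makes colocalized/single-channel count ≈ ρ,
  the observable the double-labeling experiment reports.
* **Noise**: Poisson shot noise at gain 1 photon/count plus Gaussian
  read noise (sd 2) over backgrounds of 12 (inside cells) and 2
  (outside), giving peak-signal SNR ≈ 5–10. The cell region is a
  smoothed-noise blob thresholded at the quantile matching the target
  85% covered fraction; nuclei are soft-edged disks (radius ≈ 2.9 µm)
  placed with a minimum-distance rule.
* Per-field spot counts are Poisson around the program value,
  emulating the large per-field dispersion visible in the published
  SEMs.

Determinism: every field's RNG stream derives from (base seed,
timepoint, field index), so identical configurations reproduce
identical bytes regardless of generation order, and the caller's RNG
state is never consumed.

**What the generator does not emulate** — and hence what passing tests
do *not* establish about real micrographs: optics-grade PSFs
(Airy/Gibson–Lanni), 3-D structure and focal drift, photobleaching,
uneven illumination, autofluorescence texture, clumped or mitotic
nuclei, and marker-specific antibody background. The simulation
validates the *pipeline's* correctness and calibration, not the
biology of any particular image set.

## Problem sizes used by the test suite

The suite exercises the full-size default configuration where the
claim depends on it (diameter recovery, nuclei recovery) and otherwise
scales the simulation to keep the tests fast: end-to-end rhythm
recovery runs 16 timepoints × 6 fields of 512 × 384 px with programs
scaled to the smaller field area (count mesor 33, 40% relative
amplitude), and the 50-repetition zero-amplitude negative control uses
256 × 192 px fields with two fields per timepoint, red channel only
(the count metric needs neither DAPI nor green). These sizes are the
package's own choice of simulation budget; the statistical properties
being checked do not depend on the field size.

## Known limitations

* Touching or edge-clipped nuclei are undercounted (no watershed);
  the default-field recovery stays within 15% of the configured mean.
* The integrated p-values are deliberately better calibrated — and
  therefore often larger — than those of the original meta-analysis
  tool, which combines correlated tests with plain Fisher; period
  estimates, the graded quantity, are unaffected.
* Lomb–Scargle period estimates on short windows (2.5 cycles) carry
  spectral-leakage shifts of up to ~0.1 h.
* The rolling-ball radius (5 px) is of the same order as the spot
  width, so a small fraction of each spot's skirt enters the
  background; spike height is still preserved within 10%.
* Colocalization intersects masks of the two channels as imaged; no
  chromatic-shift registration is attempted.
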