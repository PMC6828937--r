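# PunctaCycle

Quantification of punctate cytoplasmic mRNA granules — processing
bodies (PBs) and similar ribonucleoprotein foci — in multi-channel
fluorescence micrographs, and circadian rhythm analysis of their
per-field statistics.

PBs appear in immunofluorescence as near-circular foci of roughly
300–500 nm diameter. In dexamethasone-synchronized cell cultures their
number, marker signal intensity and area oscillate with periods close
to 24 h. This package implements the full quantification pipeline for
that kind of experiment:

1. **Foci detection** — the classical ImageJ-style chain on each 8-bit
   channel: Gaussian blur (σ = 0.8 px), rolling-ball background
   subtraction (radius 5 px, exact grayscale opening by a ball
   structuring element), a fixed inclusive intensity threshold (40 for
   the red channel, 35 for green — per-experiment constants, never
   adapted per image), 8-connectivity particle labeling, and a filter
   keeping particles of 3–300 px² with circularity
   4π·area/perimeter² in [0.7, 1]. At the pixel-size calibration of
   102.33 nm/px the area window corresponds to equivalent diameters
   d = 2√(A/π) of 200–2000 nm.
2. **Per-field metrics** — PB count normalized by the cell-covered
   area fraction (count for a fully covered field), mean particle
   intensity on the background-subtracted image, mean area, DAPI
   nuclei count, PBs per cell, and two-marker colocalization by
   pixelwise mask intersection.
3. **Rhythm statistics** — Kruskal–Wallis with Dunn's post hoc across
   timepoints on per-field values; three rhythm-detection methods on
   the per-timepoint mean series (Lomb–Scargle periodogram, a
   JTK-style Kendall rank-concordance scan against reference cosines,
   and an ARSER-style autoregressive spectral harmonic regression),
   each with a selection-calibrated p-value over the circadian search
   band (20–28 h); and an integrated consensus record
   (correlation-adjusted p combination, mean period, circular-mean
   phase, cosinor amplitude). Cosinor fits
   y = M + A·cos(2π(t−φ)/T) supply the plotted curves.
4. **Synthetic fields** — a seeded generator renders ground-truthed
   fields (irregular cell mask, DAPI nuclei, diffraction-limited spots
   as 2-D Gaussians with FWHM equal to the nominal diameter, Poisson
   shot noise and Gaussian read noise) whose count, per-spot
   brightness and spot cross-section follow configurable cosine
   programs, so every stage is testable without external data.

## Worked example

```r
library(PunctaCycle)

cfg <- sceneConfig(fieldWPx = 344, fieldHPx = 260,
                   countProgram = oscillationProgram(30, 12, 24, 8),
                   nucleiMean = 4, nucleiSd = 1)
field <- generateField(cfg, tH = 8, fieldIndex = 1)
foci  <- detectFoci(field$images$red, detectionParams("red"))
foci
#> ParticleSet '': 42 particles
#>   area 6.0-30.0 px^2, mean diameter 431 nm

summarizeField(foci, cellMask(field$images[c("red", "green")])$fraction,
               nucleiCount = countNuclei(field$images$dapi),
               timeH = 8, marker = "GE-1/HEDLS")
#>   pb_count_raw pb_count_norm mean_intensity mean_area_px2 nuclei_count
#> 1           42      49.21819       53.78996      14.28571            3
```

42 raw foci become 49.2 after normalizing by the 85% cell-covered
fraction; the mean background-subtracted intensity (53.8 a.u.) and
mean area (14.3 px², ≈430 nm equivalent diameter) are the other two
Table-style per-field metrics.

Rhythm analysis of the published per-timepoint mean series of
normalized PB counts (GE-1/HEDLS marker, 16 timepoints, 8–68 h):

```r
series <- pbNumberSeries()
ge1 <- series[series$marker == "GE-1/HEDLS", ]
fit <- analyzeTimecourse(timeCourse("pb_count_norm", ge1$time_h, ge1$mean))
fit$rhythm
#> RhythmResult
#>  method       p period_h phase_h amplitude
#>      LS 0.03781    23.10   4.032     90.08
#>     JTK 0.12252    24.00   0.000     88.70
#>     ARS 0.05411    24.15   2.625     88.09
#> integrated: p=0.0109 period=23.75h phase=2.26h amplitude=89.6
```

The three methods agree on a circadian period; the integrated period
of 23.75 h sits next to the 23.57 h reported for this marker (23.34 h
vs 23.33 h for DDX6). Kruskal–Wallis/Dunn comparisons are part of the
same call when per-field replicate values (rather than means) are
supplied.

The file-level pipeline (`generateTimecourse()` → `runDetect()` →
`runFull()`) orchestrates the same stages over a manifest of TIFFs,
writes per-field metrics, tidy results, a JSON summary and
cosine-fitted plots, and records a configuration hash in every
artifact. A thin CLI wrapper lives at
`inst/scripts/puncta-cycle.R` (`simulate`, `detect`, `rhythm`,
`run-all`).

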