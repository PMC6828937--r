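Package: PunctaCycle
Title: Quantification and Circadian Analysis of Punctate mRNA Granules in
    Fluorescence Micrographs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects punctate cytoplasmic foci (processing bodies and similar
    ribonucleoprotein granules) in multi-channel 8-bit fluorescence
    micrographs using a Gaussian-blur, rolling-ball background subtraction,
    fixed-threshold, size- and circularity-filtered particle analysis chain;
    summarizes per-field counts normalized by cell-covered area, signal
    intensities, areas, nuclei counts and two-marker colocalization; and
    tests per-timepoint series for circadian rhythmicity with
    Lomb-Scargle, rank-concordance (JTK-style) and autoregressive
    spectral harmonic-regression (ARSER-style) detection integrated into a
    consensus period, phase, amplitude and p-value, alongside
    Kruskal-Wallis/Dunn comparisons and cosinor curve fitting. A seeded
    synthetic-field generator with cosine programs for count, intensity and
    area provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Rcpp,
    signal,
    tiff,
    yaml,
    jsonlite,
    EBImage,
    ggplot2
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: CellBiology, Visualization, TimeCourse, Software
RoxygenNote: 7.3.3
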