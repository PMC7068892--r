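Package: lvquant
Title: Left-Ventricular Volumetry, Wall Motion and Strain Quantification
    with 4D Phantom Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-modality quantification of left-ventricular function as
    practised in small-animal cardiac imaging: M-mode Teichholz volumes,
    monoplane Simpson method of disks, stacked short-axis slice summation
    (4D ultrasound and cine CMR), the 16-segment wall motion score index,
    global and segmental strain with an SD-based dyssynchrony index, and
    the agreement statistics used to compare modalities (percentage
    Bland-Altman bias with 95% limits of agreement, single-measure
    two-way random-effects intraclass correlation, Spearman rank
    correlation with qualitative grading, and the D'Agostino-Pearson
    omnibus normality test). A seeded 4D ventricular phantom with
    parametric regional infarcts supplies ground-truth volumes and scar
    fractions, so that the geometric-assumption bias of diameter- and
    plane-based estimators after regional infarction can be measured
    against slice-based estimators in silico.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
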