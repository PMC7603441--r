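Package: arcial
Title: Sassouni Arcial Analysis for Two-Dimensional Mandibular Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the adapted Sassouni arcial analysis of lateral
    cephalometric radiographs: construction of the four horizontal
    cephalometric planes, location of the theoretical convergence point O,
    anterior and posterior arcs, and geometric estimation of the mandibular
    landmarks gonion and pogonion from cranial-base landmarks. Includes the
    accompanying validation statistics (Bland-Altman agreement with 2-sd
    limits, two-way mixed average-measures intraclass correlation,
    Ryan-Joiner normality screening, Spearman correlation with Fisher-z
    intervals, ordinary least-squares prediction of mandibular body length
    from anterior cranial base length, and palate-by-mandible shape
    contingency analysis with Fisher's exact test and Bonferroni
    correction), a synthetic cephalometric cohort generator with known
    ground truth, and a pipeline that reproduces the full validation study
    on simulated cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
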