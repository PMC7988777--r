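Package: notoquant
Title: Quantitative Scoring of Notochord Lesions and Skeletal Phenotypes in
    Larval Zebrafish Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-analysis pipeline for scoring fluorescence lesions along
    the larval zebrafish notochord: intensity-threshold segmentation of the
    notochord, degree-6 polynomial centerline fitting, arc-length intensity
    profiling along the fitted curve, mean-profile severity scoring, peak
    based lesion calling and fish classification, and rank-based group
    comparison (Kruskal-Wallis omnibus, Dunn's post hoc with Bonferroni
    adjustment, Mann-Whitney). Also provides the accompanying skeletal
    quantifications (vertebral fusion/cleft severity rubric, two-phantom
    tissue mineral density calibration, RGB stain channel means) and a
    synthetic-data generator with full ground truth so every stage of the
    pipeline can be validated without raw microscope images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
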