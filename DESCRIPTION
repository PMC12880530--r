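Package: caa3d
Title: Three-Dimensional Surface-to-Depth Quantification of Cerebral
    Amyloid Angiopathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cerebral amyloid angiopathy (CAA) in three
    dimensions along the arterial network: vascular-unit depth labeling of
    traced skeletons (LMA, D0, D0-D1, D1, ...), segment-wise amyloid-beta
    and smooth-muscle-actin classification, vascular amyloid load
    statistics, D0 external-diameter morphometry, length-normalized
    perivascular plaque density in a 10-100 micrometre band, dyshoric
    change flagging, and a nonparametric test battery (quartiles,
    Mann-Whitney U, Kruskal-Wallis, Steel-Dwass). Ships a synthetic cohort
    generator that emulates light-sheet imaging of cleared cortical blocks
    so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
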