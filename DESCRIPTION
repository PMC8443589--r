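Package: mpskit
Title: Quantitative Analysis for Liver Microphysiological System Fibrosis Models
Version: 0.1.0
Authors@R:
    person("Lena", "Ardal", email = "lena.ardal@example.org", role = c("aut", "cre"))
Description: Analysis machinery for organ-on-chip (microphysiological system,
    MPS) studies of non-alcoholic steatohepatitis: automated quantification of
    fibrosis markers (alpha-smooth-muscle actin, collagen-I) from confocal
    images of scaffold-grown liver microtissues (tile stitching, scaffold
    detection, fixed ROI placement, focus-plane selection, microtissue
    segmentation and background-subtracted intensity measurement); in-vitro
    pharmacokinetics for dose translation (recovery, equilibrium-dialysis
    protein binding, first-order half-life fitting, spike-to-nominal dosing
    regimen simulation, clinical-dose anchoring); transcriptomic marker-set
    concordance scoring with Fisher's-exact enrichment; and soluble-biomarker
    panel analytics (detection filtering, ANOVA with Sidak comparisons,
    z-score matrices). A seeded synthetic-fixture generator emulates slide
    mosaics, defocused z-stacks, drug decay series, expression matrices and
    biomarker panels with machine-readable ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
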