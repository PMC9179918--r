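Package: jointQMRI
Title: Quantitative MRI Biomarkers and Robust Statistics for
    Experimental Osteoarthritis Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Voxel-wise magnetic resonance relaxometry and joint-tissue
    morphometry for small-animal osteoarthritis studies, together with
    the robust statistics used to analyse them. Provides variable
    flip-angle T1 and multi-echo T2 mapping of articular cartilage,
    six-segment cartilage parcellation with volume and thickness
    measurement, subchondral trabecular bone morphometry (bone volume
    fraction, trabecular thickness, spacing and number, 2D/3D
    box-counting fractal dimensions), a trimmed-means heteroscedastic
    two-way ANOVA with interaction, a noncentral-t power and effect-size
    solver, and synthetic phantom generators with analytic ground truth
    so every stage can be validated without scan data. Volumes are read
    and written as NIfTI with JSON acquisition sidecars.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    withr,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
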