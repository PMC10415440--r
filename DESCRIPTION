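Package: wfsep
Title: Water-Fat Separation and Proton Density Fat Fraction Mapping for
    Chemical-Shift-Encoded MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative water-fat separation of multi-echo
    chemical-shift-encoded (CSE) gradient-echo MRI at desk scale: the
    multi-peak fat spectrum signal model with R2* decay and off-resonance,
    proton density fat fraction (PDFF) computation, a seeded synthetic
    abdominal phantom generator, a voxel-wise VARPRO nonlinear
    least-squares fit, a multi-decoder U-Net with self-attention
    (and a single-decoder U-Net comparator) trained with masked
    mean-absolute-error loss and a cosine learning-rate schedule, and
    agreement statistics (ROI summaries, least-squares regression,
    Bland-Altman limits of agreement, one-way ANOVA with Tukey HSD).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
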