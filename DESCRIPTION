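Package: gbeorient
Title: Myosin Orientation Dynamics During Drosophila Germband Extension
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of junctional myosin-II anisotropy during
    Drosophila germband extension on 2D cylindrical pullback maps of the
    embryo surface. Provides segmentation-free detection of myosin-rich
    junctions by a windowed Radon transform, nematic orientation fields and
    circular statistics, tissue-flow analysis (vorticity, rotation rate,
    Lagrangian advection, temporal autocorrelation), pair-rule-gene stripe
    segmentation and gradient regression, a one-parameter static-source
    relaxation model for the myosin/DV-axis angle with effective-lifetime
    fitting, FRAP recovery-curve models, and a synthetic-embryo generator
    so that every stage of the analysis is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    EBImage,
    tiff,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
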