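Package: CatSperQuant
Title: Quantification of CatSper1 Nanodomain Organization in 3D Sperm Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An image-analysis pipeline for in situ 3D fluorescence imaging
    of sperm in cleared oviduct tissue. Simulates multi-channel training
    volumes containing sperm, somatic-nucleus and noise signatures with
    exact ground truth; trains and evaluates a frame-based classifier that
    localizes sperm by coordinate-matched sensitivity and specificity;
    linearizes flagellar CatSper1 signals normalized to the paired sperm
    nucleus and measures signal-continuity breakpoints; quantifies the
    quadrilateral organization of CatSper1 nanodomains from tail
    cross-sections via an 80-area angular intensity profile and its
    peak-minus-valley delta statistic; and compares sperm populations
    across oviduct regions with rank-based and parametric group tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    nnet,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, CellBiology, Visualization, Classification,
    ImageImport
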