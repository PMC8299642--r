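Package: tuberphen
Title: Multi-Modal Phenotyping of Potato Shoots, Leaves and Tubers Under
    Water Deficit
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computational toolkit for non-invasive drought phenotyping of
    potato (Solanum tuberosum). Extracts shoot morphology and greenness
    traits (projected area, convex hull area, height/width, Excess Green
    index) from top- and side-view RGB images; inverts CPMG transverse
    relaxation decays into continuous T2 distributions by maximum-entropy
    and Tikhonov-regularised non-negative least squares, with vacuolar
    peak assignment and split/merge tracking across leaf development;
    segments, counts, measures and longitudinally tracks tubers in 3-D MR
    volumes with diameter-based yield filtering; and provides the leaf
    water status, gravimetric watering and ANOVA/Tukey compact-letter
    utilities the methodology relies on. Seeded synthetic-fixture
    generators with known ground truth make every analysis testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    pracma,
    RNifti,
    tiff,
    png,
    igraph
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
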