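Package: cephert
Title: Cascaded Regression-Tree Localization of Cephalometric Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and applies cascaded ensembles of gradient-boosted
    regression trees to localize 26 anatomical landmarks on lateral
    cephalogram-like images, using shape-indexed pixel-difference features.
    Includes a deterministic synthetic cephalogram generator with perfect
    annotations, landmark-consistent affine and elastic data augmentation,
    seven derived angular diagnostic features (SNA, SNB, ANB, incisor
    inclinations, mandibular plane angle, soft-tissue convexity), and
    experiment harnesses for parameter sweeps, transform-novelty assessment,
    augmentation-gain curves, and per-landmark error directionality.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
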