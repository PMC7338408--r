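Package: ductflux
Title: Quantification Toolkit for Vascularized Duct-on-Chip Imaging Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Image-based quantification for microfluidic organotypic models
    that pair a perfused endothelial microvessel with an epithelial duct in a
    collagen hydrogel. Implements diffusive-permeability estimation from
    dextran time-lapse stacks via a dynamic mass-conservation fit, junctional
    (cortical) actin line-profile scoring, Golgi polarity angles, Ki67
    fractions, vessel diameter and sprout counting, duplicate-spot cytokine
    array densitometry with cross-membrane normalization, Hertzian
    nanoindentation fitting of hydrogel stiffness, and finite-difference
    diffusion solvers for transmural efflux and inter-channel morphogen
    gradients. A synthetic-data module generates every input with embedded
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    Matrix,
    minpack.lm,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
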