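Package: octavista
Title: Quantitative Flow Velocimetry for OCT Angiography with Variable
    Interscan Times
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for variable interscan time analysis (VISTA)
    of optical coherence tomography angiography (OCTA). Implements
    ammonite-scan acquisition geometry and timing, complex-correlation
    decorrelation estimation from repeated frames, en-face slab projection
    between retinal boundary surfaces, multi-scale optimally-oriented-flux
    vessel segmentation with per-pixel diameter estimation and three-class
    labelling, per-pixel saturating-exponential decorrelation fitting
    yielding a blood-flow-velocity surrogate (the flow parameter 1/tau),
    region-of-interest quantification, false-colour rendering, and a
    synthetic vessel-phantom simulator with known ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
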