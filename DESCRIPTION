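Package: sarcoquant
Title: Quantification Pipelines for Nanobody-Labelled Muscle Imaging
Version: 0.1.0
Authors@R: person("Sarcoquant", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Band-level quantification of fluorescence microscopy data from
    striated muscle labelled with small-probe (nanobody) stainings:
    line-profile background subtraction, peak detection and Gaussian band
    fitting; exponential decay-length estimation of label penetration over
    imaging depth; dual-channel sarcomere length and epitope-span metrology;
    FRAP recovery quantification by ROI ratio normalization; staining-intensity
    comparison for targeted-degradation experiments; and global 1:1 Langmuir
    fitting of biolayer-interferometry sensorgram series. Ships forward models
    that simulate every input (striated profiles and images, depth-attenuated
    z-stacks, FRAP movies, control/knockdown pairs, sensorgrams) with known
    ground truth, so each pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
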