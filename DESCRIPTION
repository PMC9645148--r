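Package: cardioseg
Title: Cardiac Cine-MRI Segmentation with Low-Rank Self-Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end semantic segmentation of short-axis cardiac cine
    magnetic resonance sequences. Locates the heart by combining a temporal
    standard-deviation filter, the four-step Canny edge detector and a Hough
    circle transform, crops a 128x128 window centred on the detected aorta,
    segments right atrium, left atrium and aorta with an encoder-decoder
    network carrying a low-rank tensor self-attention reconstruction (LRSAR)
    bottleneck, refines boundaries with a grid conditional random field, and
    scores results with the six standard overlap metrics. A synthetic
    beating-heart phantom generator provides ground-truthed cine sequences
    so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    RNifti,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'canny.R'
    'cine-io.R'
    'utils.R'
    'crf.R'
    'nn-layers.R'
    'esa-unet.R'
    'hough.R'
    'metrics.R'
    'phantom.R'
    'train.R'
    'roi.R'
    'pipeline.R'
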