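Package: pancseg
Title: Pancreas Segmentation and Fat Quantification from Abdominal CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Segmentation of the pancreas from abdominal computed tomography
    using a dual self-attentive transformer U-Net: a CNN encoder/decoder
    wrapped around windowed spatial plus spectral (frequency-domain)
    self-attention blocks, with a mask-classification decoder that refines
    learned organ queries by iterative masked cross-attention and is trained
    with a Hungarian-matched binary-mask plus classification loss. Includes
    deterministic CT preprocessing (resampling, percentile Hounsfield-unit
    clipping, Laplacian-based sharpening, Gaussian-weighted sliding-window
    fusion), surface-distance segmentation metrics (HD95, ASSD), pancreatic
    volume and fat-volume-fraction estimation by Hounsfield-unit
    thresholding, and a seeded CT phantom generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tibble,
    ggplot2,
    generics,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
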