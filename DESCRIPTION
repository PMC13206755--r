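Package: fundseg
Title: Adapter-Based Segmentation of Optic Disc and Cup in Fundus Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint optic-disc and optic-cup segmentation for retinal fundus
    photographs by parameter-efficient adaptation of a frozen ViT-large
    encoder. Provides the full network (pre-adapter, per-block bottleneck
    adapters, mask-transformer decoder, CBAM-gated skip connections,
    progressive upsampling post-adapter), a combined Dice + cross-entropy
    training loop with AdamW, segmentation metrics (Dice, HD95, average
    surface distance, bootstrap confidence intervals), optic-disc-centered
    preprocessing with exact restoration to original coordinates, and a
    synthetic fundus phantom generator so the whole pipeline can be
    exercised on a single CPU without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    Matrix,
    Rcpp,
    EBImage,
    png,
    yaml,
    jsonlite,
    tibble,
    generics,
    ggplot2,
    rlang,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
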