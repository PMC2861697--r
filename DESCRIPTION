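Package: regspline
Title: Penalized-Spline Models of Regulatory Site Influence on Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits penalized B-spline (P-spline) influence functions that map
    the signed distance between a transcription-factor binding site and a
    transcription start site to the site's additive contribution to log gene
    expression. Includes competing model variants (uniform weighting,
    conservation-weighted, per-regulator influence weights, ChIP-affinity
    weighting), site-to-gene association under multi-gene and nearest-gene
    assumptions, conservation scoring of bound regions with data-driven
    threshold selection, a train/test evaluation protocol with bootstrap
    confidence bands and permutation controls, and a synthetic-data generator
    emulating tissue-specific ChIP binding and expression data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    splines,
    stats,
    tools,
    utils,
    graphics,
    jsonlite,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
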