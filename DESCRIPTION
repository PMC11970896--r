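Package: deimmune
Title: Preference-Optimized Protein Sequence Design with Reduced MHC-I Immune Visibility
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for designing protein sequences with fewer predicted MHC
    class I epitopes while preserving a template backbone fold. Provides a
    position-weight-matrix (PWM) presentation classifier calibrated against a
    reference predictor, an immune-visibility metric that counts presented
    8-10-mer peptides in a sequence, a miniature structure-conditioned
    autoregressive sequence-design model with arbitrary-order decoding, a
    direct-preference-optimization (DPO) alignment loop that tunes the model
    toward low-visibility designs, and design-evaluation utilities
    (candidate filtering, TM-score, sequence recovery, trade-off summaries).
    A synthetic-data module generates toy backbones and a deterministic
    motif-based reference presentation oracle so the whole pipeline runs at
    desk scale with no external services.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    bio3d,
    seqinr,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
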