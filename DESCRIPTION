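Package: pepvar
Title: Predicted Peptide Variant Discovery from MS Peptidomics Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers candidate bioactive peptides from mass-spectrometry
    peptidomics experiments. Observed peptides are mapped onto their precursor
    protein backbones, positional intensity profiles are aggregated into
    fourteen cluster-structure features, and an L2-regularised logistic
    regression (the PPV model) is trained on known annotated peptides with
    group-aware nested cross-validation. Includes two-engine (MaxQuant/Mascot)
    table merging via a log-linear transfer function, in-silico assembly of
    overlapping degradation fragments into full-length candidates,
    Kullback-Leibler flanking-motif logos, amidation-motif enrichment, rank
    recovery and enrichment evaluation, and a synthetic peptidome simulator
    with planted dibasic-flanked peptides and geometric degradation ladders.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    glmnet,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
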