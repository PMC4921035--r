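Package: spikeqc
Title: Quality Control of ERCC Spike-In Control Pools from a Modified Latin
    Square Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Composite testing scheme for evaluating pools of External RNA
    Controls Consortium (ERCC) spike-in controls mixed under a modified Latin
    square design. Provides the pool design (nominal abundances, mixing
    proportions, pairwise fold changes), dose-response model fitting (a
    Langmuir isotherm for hybridization microarrays, a unit-slope linear
    model for RNA-Seq), response-curve outlier flagging at a chosen
    confidence level, per-control slope and Spearman monotonicity screening,
    linear-region demarcation from the model's slope curve, pairwise
    Bland-Altman (MA) ratio analysis with model-derived ratio-compression
    curves, dynamic-range summaries, and a synthetic signal-table generator
    so the whole pipeline is testable without platform data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
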