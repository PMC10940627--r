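Package: morphodtt
Title: Disparity Through Time and Rates of Evolution from Discrete
    Morphological Characters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying morphological disparity through time from
    cladistic character matrices and time-calibrated phylogenies. Computes
    Gower and maximum observable rescaled distances (MORD) between taxa
    scored for discrete characters, ordinates them by principal coordinates
    analysis, reconstructs ancestral states under an equal-rates Mk model so
    that internal nodes can occupy the same morphospace as tips, slices the
    tree through time under gradual-split or punctuated models, and
    summarises disparity per time bin with bootstrap and rarefaction.
    Character-change rates are estimated per time bin or per clade by
    Poisson models with exhaustive AICc model selection, and environmental
    correlates are assessed by ARIMA detrending with residual
    cross-correlation. A synthetic-data generator with known truth supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    jsonlite
Config/testthat/edition: 3
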