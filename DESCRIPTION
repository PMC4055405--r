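Package: mpingr
Title: Simulation and Inference of mPing Transposition During Rice Ontogeny
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying somatic and germinal transposition of the
    rice MITE mPing through developmental time. Provides a configurable
    cell-lineage model of rice embryogenesis that maps transposition events
    to the set of sampled tissues carrying them (and inverts that map into
    candidate timing windows), a stochastic cut-and-paste transposition
    simulator with expression-threshold-gated rates, excision repair,
    meiosis and crossing, in-silico versions of the field assays
    (transposon display with selective bases, locus-specific SCAR PCR,
    CAPS digestion genotyping, 2^-ddCt expression and copy-number qPCR),
    the de novo insertion/excision calling and tissue-specificity
    classification pipeline, inheritance scoring, and cohort statistics
    including the Steel-Dwass all-pairs nonparametric comparison. Seeded
    generators emulate selfed ontogeny cohorts, reciprocal F1 populations,
    and a landrace panel so every stage runs end-to-end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
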