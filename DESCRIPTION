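Package: tailprop
Title: Cross-Species Transcriptomics and Morphometrics of Tail Vertebral Proportion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify genes associated with disproportionate
    vertebral elongation from cross-species growth-cartilage RNA-seq, and to
    quantify the vertebral morphometrics that motivate the comparison.
    Implements negative-binomial Wald differential expression with
    median-of-ratios size factors and cross-species gene-length offsets,
    prediction-interval classification of disproportionately differentially
    expressed genes, hypergeometric term enrichment and Fisher-exact gene-set
    overlap, vertebral length measurement from one-dimensional micro-CT
    intensity profiles, growth-plate histomorphometry summaries, and a
    synthetic-data generator with planted ground truth that emulates a
    mouse/jerboa tail study design end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr
Config/testthat/edition: 3
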