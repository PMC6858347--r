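Package: drivermed
Title: Mediation-Based Prioritization of Copy-Number Driver Genes from
    Paired Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates somatic copy-number alterations (or other binary
    epi-DNA alterations) with matched gene-expression profiles to identify
    cis and trans differential-expression signatures of each alteration,
    rank cis genes by the weighted fraction of trans-gene expression they
    statistically mediate (Sobel test), and call the Rank-1 candidate
    driver gene of each alteration. Includes hypergeometric gene-set
    enrichment of alteration signatures, Fisher-test validation against
    driver-gene references and dependency screens, forward simulation of
    the mediation test's operating characteristics, and bootstrap
    assessment of ranking reproducibility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
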