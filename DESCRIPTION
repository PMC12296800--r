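Package: warkeys
Title: Keyness Analysis of Trauma Testimony Corpora with an Informative
    Dirichlet Prior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the lexicon of a corpus of wartime
    testimony narratives against a pre-war reference corpus. Ingests a
    two-format corpus release (a narrative-level CSV with participant
    demographics and psychometric totals, and a token-level CoNLL-U table
    with lemmas and morphosyntax), applies exclusion, de-identification
    and stopword procedures, and computes per-lemma keyness as the
    log-odds ratio with an informative Dirichlet prior (LORIDP),
    standardized to z-scores with Bonferroni family-wise control. A
    synthetic-corpus generator with Zipf-Mandelbrot lemma frequencies and
    planted log-odds enrichments makes every pipeline stage and
    statistical property testable without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
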