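Package: famlr
Title: Kinship Likelihood Ratios and Relationship Distinguishability for
    Familial Searching
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Evaluates forensic familial identification with unlinked
    autosomal markers. Computes pairwise-relationship likelihood ratios
    with a coancestry (theta) correction via the sequential Dirichlet
    ("urn") genotype-pair model, delta-method confidence intervals on the
    log likelihood ratio under a Dirichlet allele-frequency uncertainty
    model, gene-dropping and urn-model simulation of related and
    unrelated genotype pairs, panel summaries (gene diversity, profile
    entropy, Weir-Cockerham FST from allele-frequency tables), and the
    distinguishability, power and false-positive-rate statistics used to
    compare lower-confidence-limit distributions across structured
    populations.
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
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
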