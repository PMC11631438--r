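Package: kinfolk
Title: De Novo Mutation Calling with Sibling Surrogate Parents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls germline de novo mutations (DNMs) in nuclear families where
    one or both parents are missing, by using siblings as "surrogate parents":
    identity-by-descent (IBD) segments shared between siblings stand in for the
    missing parental genomes, and Mendelian violations are called only inside
    the accessible regions those segments define. Includes a native sibling IBD
    scanner over phased common variants, parental-origin labelling, accessible-
    region geometry with theoretical callable fractions, a filter stack
    (population panel, familial sharing, mutation clusters, variant allele
    frequency), 1-mer mutation spectrum classification, per-trio mutation rate
    estimation, a parental-age linear model for expected per-type DNM burdens
    with exact one-tailed Poisson burden tests, mutator effect-size and
    detection-power calculations, a generation-time regression for recombinant
    inbred mouse strains, and a genotype-level pedigree simulator with
    recombination, gene conversion and sequencing-depth sampling that
    benchmarks the caller against known truth.
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
    rlang,
    stringr,
    readr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
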