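Package: repeatclean
Title: CRISPR-Cas9 Guide Design and Depletion Simulation for Repetitive DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design genome-scale Cas9 (NGG) guide RNA sets against repetitive DNA
    while protecting genes and open-chromatin regions: PAM-site scanning, sequence
    quality filters, mismatch-tolerant off-target exclusion, greedy selection under
    cleavage-site count and spacing constraints, pool/group assignment and gRNA
    dosing. Includes a synthetic-genome generator with planted diverged repeat
    families, a sequencing-library depletion simulator, and evaluation of depletion
    and low-coverage genotypability (read-count variation, log2 coverage variation
    with zero-coverage exclusion bookkeeping, callable positions at a depth
    threshold, and a binomial model of heterozygote detection).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    withr,
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    Rsamtools,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
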