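Package: abcfam
Title: Annotation and Comparative Analysis of ABC Transporter Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies and classifies ATP-binding cassette (ABC)
    transporters in predicted proteomes. Candidate proteins are detected by
    a nucleotide-binding-domain (NBD) profile search (external HMMER3
    domtblout tables or a built-in PSSM local aligner), assigned to ABC
    families A-H by best-hit voting and e-value-gap rules against a
    family-labelled reference database, split into ABC-B full and half
    transporters by NBD count, and filtered by length and proteome (BUSCO)
    quality. Downstream helpers compare family sizes across taxonomic
    groups (tie-corrected Kruskal-Wallis with Conover post-hoc comparisons
    and compact letter displays), normalize expression to TPM with per-gene
    z-scores, and compute Schneider-Orelli corrected mortality and
    delta-delta-Ct fold changes. A synthetic-proteome generator plants
    ABC genes with known truth labels for end-to-end benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    generics,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
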