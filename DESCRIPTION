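Package: mitodiv
Title: Correlates of Mitochondrial Synonymous Diversity Across Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tidyverse-native pipeline for asking what shapes within-species
    mitochondrial genetic diversity in comparative datasets such as birds.
    Estimates synonymous and nonsynonymous nucleotide diversity (piS, piN,
    piN/piS) from in-frame codon alignments by Nei-Gojobori site counting
    under the vertebrate mitochondrial code, tests phylogenetic signal with
    Pagel's lambda, computes Felsenstein's phylogenetically independent
    contrasts of log-transformed traits, and correlates and regresses
    diversity against life-history and demographic variables through the
    origin. Population substructure and cryptic species are detected with a
    single-threshold generalized mixed Yule-coalescent (GMYC) model on
    ultrametric gene trees, after which diversity is re-estimated from the
    largest within-species cluster. A synthetic-data generator simulates
    complete studies (Yule species trees, Kingman genealogies, codon
    sequences under purifying selection, correlated Brownian-motion traits)
    so every stage is testable without downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
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
    withr
Suggests:
    optparse,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
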