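Package: quantbac
Title: Design and In Silico Validation of Broad-Coverage Bacterial 16S
    rRNA Gene qPCR Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for designing and validating broad-coverage
    (pan-bacterial) 16S rRNA gene quantitative real-time PCR assays.
    Profiles multiple sequence alignments into per-column nucleotide
    distributions with gap filtering and Simpson-based diversity scores to
    locate conserved primer/probe sites; enforces degeneracy rules and
    computes salt-adjusted melting temperatures for degenerate
    oligonucleotides; runs an in silico coverage pipeline over
    taxonomy-annotated 16S collections with IUPAC-aware perfect-match
    testing under stringent and relaxed criteria and stepwise
    phylum/genus/species dereplication; and implements qPCR quantification
    arithmetic (2^dCp plasmid-standard normalization, standard-curve
    efficiency and r-squared, inter/intra-run coefficients of variation
    with triplicate outlier exclusion, and bacteria-to-human ribosomal
    copy and genome-equivalent ratios). Synthetic-data generators with
    exact ground truth make the whole pipeline testable without any
    sequence database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
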