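Package: evquant
Title: Label-Free Quantification and Comparison of Extracellular Vesicle
    Proteomes from Peptide Identification Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Spectral-count label-free proteomics pipeline built around the
    exponentially modified protein abundance index (emPAI). Performs in-silico
    tryptic digestion of a FASTA protein database to obtain observable-peptide
    counts, converts per-run identified-peptide counts into emPAI and
    normalized molar percentages (M%), aggregates replicate runs with
    missing-not-zero semantics, and compares two groups by unique/shared
    partition, fold-change classification at a configurable cutoff,
    per-protein t-tests with Holm-Sidak or Benjamini-Hochberg adjustment,
    volcano tables, protein-signature matching, and within-family composition
    profiles. Includes gene-set over-representation analysis against GMT
    collections with kappa-score grouping of enriched terms, a synthetic-data
    generator with known ground truth for validating the whole chain, and an
    end-to-end pipeline runner with a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
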