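Package: foldrank
Title: Consensus Ranking, Refinement Control, and Evaluation for Protein
    Structure Model Pools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the decision layer of an AlphaFold2-era protein
    tertiary structure prediction pipeline: reading and writing CA-level
    structural models with per-residue confidence (pLDDT in the B-factor
    column), pairwise structural similarity metrics (TM-score, GDT-TS,
    CA-lDDT) with Kabsch superposition, consensus quality assessment of
    model pools (APOLLO pairwise-similarity scores and pLDDT hybrids),
    pool-diversity and evaluation statistics (ranking loss, per-target
    correlation, weighted z-score combination), A3M multiple sequence
    alignment handling with identity filtering and Neff, conversion of
    structure-search hits into alignment rows for MSA augmentation,
    template database curation, an iterative structure-alignment-based
    refinement controller with pluggable search and folding backends,
    assembly-aware monomer model integration and region grafting, MSA and
    template sampling plans, and deterministic synthetic fixtures and mock
    backends so the whole workflow runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
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
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
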