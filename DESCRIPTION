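Package: crykit
Title: Retrieval, Alignment and Conservation Analysis of Bacillus
    thuringiensis Cry Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A headless toolkit for working with Bacillus thuringiensis
    crystal (Cry) insecticidal proteins. Parses the Bt toxin nomenclature
    table, retrieves protein records from NCBI Entrez (efetch, GBSet XML)
    with a fully offline fixture mode, stores extractions as versioned
    data packages, catalogs deposited 3D structural models (PDB/PMDB),
    generates per-domain FASTA files, drives external multiple sequence
    aligners (Clustal Omega, ClustalW, MUSCLE, MAFFT) or a built-in
    pairwise Needleman-Wunsch aligner, and classifies every column of a
    pairwise alignment as conserved, conserved mutation, semi-conserved
    mutation or non-conserved, producing difference lists, per-protein
    percentage statistics and structured or HTML reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tibble,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
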