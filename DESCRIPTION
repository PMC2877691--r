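Package: bsclone
Title: Clone-Level Analysis of Bisulfite Sequencing Data from Unique and
    Repetitive Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of subcloned bisulfite-PCR sequencing reads against a
    unique genomic reference or a repeat-family consensus. Reads are oriented
    and vector-trimmed by bisulfite-aware global alignment to the in-silico
    converted reference, quality-filtered on sequence identity, bisulfite
    conversion rate, gaps and unresolved bases, and CpG methylation states are
    called with a guanine-anchored rule robust to thymine indels at
    homopolymer stretches. Clonal PCR duplicates are detected by cytosine
    pattern comparison with N-wildcarding, in a strict and a
    conversion-artifact-aware mode. A consensus (repeat) mode reports
    methylated CpGs at consensus and non-consensus positions and estimates
    overall methylation with a CG-to-CA mutation correction. A bundled
    simulator generates bisulfite clone datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
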