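Package: tebench
Title: Simulation and Base-Level Benchmarking of Transposable Element Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking de novo transposable-element (TE)
    detection software. Simulates genomes with a known TE content by
    inserting mutated, truncated and nested copies of consensus sequences
    into a random base sequence, emitting the genome as FASTA together
    with an exact ground-truth annotation in GFF3. Scores any predicted
    repeat annotation against a reference at single-base resolution
    (confusion matrix, Matthews correlation coefficient, coverage by
    sequence identity, repeat landscapes, track tables for plotting), and
    audits de novo consensus models against reference families (alignment
    mapping, perfect/good/present/not-found classification, detection of
    homodimeric and chimeric models).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
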