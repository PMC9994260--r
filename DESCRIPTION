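Package: editscan
Title: Quantify A-to-I RNA Editing from Strand-Specific RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies adenosine-to-inosine (A-to-I) RNA editing
    from strand-specific (dUTP-protocol) RNA sequencing of bacteria and their
    phages. Edited adenosines read out as A-to-G mismatches against the
    reference genome, so the package filters aligned reads (rRNA, multi-mapper,
    indel-containing, and sense-strand reads are discarded), builds per-position
    base pileups, computes per-site editing fractions and transcriptome-wide
    mismatch-class rates, calls edited sites with an exact binomial test under
    Benjamini-Hochberg control, compares conditions across infection
    timepoints, and reports user-supplied target loci. A synthetic-data module
    generates miniature host-plus-phage references and strand-specific reads
    with known injected editing, sequencing error, rRNA load, and multi-mapping
    decoys, so every stage is verifiable offline against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
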