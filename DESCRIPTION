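Package: polylnc
Title: Origin and Epigenomic Dynamics of Long Non-Coding RNAs in Hybrid and
    Allopolyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for studying how long non-coding RNAs
    (lncRNAs) arise and behave during interspecific hybridization and
    allopolyploidization. The package classifies assembled transcripts into
    lincRNA, natural antisense, and intronic lncRNA candidates; chains
    collinear anchor-gene synteny blocks between (sub)genomes and labels each
    lncRNA locus as syntenic-transcribed (ST), syntenic allelic-transcribed
    (SA), syntenic to a coding gene, or non-syntenic; attributes transposable
    element (TE) overlap by family with a longest-TE rule and tests family
    enrichment between lncRNA classes; compares hybrid expression against an
    in silico mid-parent mix with Up/Down/Equal calls; and profiles small-RNA
    coverage and bisulfite DNA methylation (CG/CHG/CHH) over features,
    including differentially methylated region (DMR) calling and
    methylation-expression association. A synthetic-data module generates
    miniature diploid, F1-hybrid, and allotetraploid genomes with planted
    ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    data.table,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
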