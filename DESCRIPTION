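Package: mirmzt
Title: Small RNA Annotation, isomiR Classification and Expression
    Profiling Across the Maternal-to-Zygotic Transition
Version: 0.1.0
Authors@R:
    person("Maintainer", "mirmzt", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for bulk small RNA-seq
    analysis of early embryogenesis experiments: adapter/quality/length
    preprocessing and read collapsing, exact-match genome alignment with
    fractional multi-mapper weights, priority-ordered small-RNA class
    annotation (miRNA, structural RNA, cis-NAT, transposon, exon, intron,
    intergenic), classification of miRNA reads into canonical, noncanonical
    (templated isomiR) and 3' non-templated addition (NTA, tailing)
    isoforms, TMM-normalized negative-binomial GLM likelihood-ratio
    differential expression, hierarchical clustering of expression profiles
    into developmental classes, and hypergeometric/Fisher gene-list overlap
    statistics. A synthetic-data module generates a toy genome, annotation
    layers and FASTQ libraries with a complete ground-truth sidecar, so the
    whole pipeline is exercised without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
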