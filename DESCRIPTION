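Package: nanoiso
Title: Isoform Discovery, Quantification and Differential Transcript Usage
    for Long-Read RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies and quantifies transcript isoforms from
    genome-aligned long cDNA reads (Oxford Nanopore style spliced
    alignments). Reads are grouped by splice-junction chain, corrected
    against a reference annotation, merged within configurable junction and
    transcript-end tolerances, collapsed when they look like truncated
    fragments of longer forms, and filtered to a high-confidence isoform
    catalog; every read is then assigned to one transcript of the combined
    known-plus-novel catalog to produce a transcript-by-sample count matrix
    and full-length coverage metrics. Downstream tools provide SQANTI-style
    structural classification of the catalog, expression filtering,
    differential transcript usage testing (per-transcript relative-usage
    t-tests with gene-level Simes aggregation, Benjamini-Hochberg and
    stage-wise adjustment), and evaluation against ground truth. A
    sequins-like simulator generates toy annotations, two-mix abundance
    designs and spliced read alignments with truncation and jitter, so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    limma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
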