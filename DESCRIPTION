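Package: ploidyseq
Title: Differential Expression and Promoter Motif Enrichment for Ploidy
    RNA-Seq Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a replicate-overlap differential-expression pipeline for
    two-condition RNA-seq count data without within-condition replicates, as used
    to compare haploid and tetraploid yeast transcriptomes: reciprocal one-sided
    binomial tests on per-gene read frequencies, fold-change ranking with
    equal-top-N overlap between replicate pairs and a hypergeometric overlap
    test, hypergeometric gene-set (GO term) enrichment against an expressed-gene
    background, and a promoter motif-enrichment scanner with log-likelihood
    matrices, an adaptive score cutoff and a binomial enrichment test. A
    synthetic-data generator produces count tables, annotated toy genomes and
    promoter sequences with planted fold changes and motif sites so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
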