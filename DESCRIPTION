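Package: ocrenrich
Title: Enrichment of GWAS Risk Variants in Open Chromatin and
    Motif-Defined Peak Subsets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tests whether trait-associated index variants and their
    linkage-disequilibrium proxies are concentrated in open chromatin
    regions (e.g. ATAC-seq peaks) and in subsets of those regions defined
    by transcription-factor motif content.  Implements two independent
    enrichment statistics -- a locus-shift (circular permutation) test and
    a matched-control-variant test with an exact Poisson-binomial null --
    together with interval arithmetic and Jaccard similarity for
    annotation sets, r-squared/LD-proxy expansion from haplotype panels,
    position-weight-matrix scanning calibrated by an exact score
    distribution, k-mer based de novo motif discovery, motif-based peak
    subsetting, and a synthetic-data generator with planted enrichment so
    the whole workflow can be exercised end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
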