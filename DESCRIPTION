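Package: introgmap
Title: Backcross Introgression Mapping and Strain Comparison for Haploid Fungi
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping traits introduced into a recurrent genetic
    background by repeated backcrossing of haploid fungi, modelled on the
    restoration of female fertility in Trichoderma reesei QM6a from the
    fertile isolate CBS999.97. Provides a forward simulator of haploid
    meiosis (Haldane model) with selection at a fertility and a mating-type
    locus, synonymous/nonsynonymous SNP annotation against gene models,
    sliding-window detection of donor introgression blocks and clustered
    high-nonsynonymous regions, expected-retention arithmetic and exact
    marker-trait association tests, plus an expression/growth profiling
    layer with one-way ANOVA, fold-change filters, hierarchical pattern
    clustering and hypergeometric category enrichment. All stages are
    testable on synthetic data emitted in standard formats (VCF, GFF3,
    FASTA, TSV, BED).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
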