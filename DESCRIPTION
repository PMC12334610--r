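Package: isoallele
Title: Allele-Level Isoform Usage Analysis of Heterozygous Splicing
    Variants from Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tests whether a heterozygous putative splice-altering variant
    changes isoform usage between its two alleles, using splice-aware
    aligned long reads. Reads spanning the variant are partitioned into
    alleles at allele-informative SNVs (or phased into haplotypes by
    minimum error correction), collapsed into isoform groups by their
    splice-junction chains, and compared per isoform with two-sided exact
    tests under Bonferroni control across variants. Includes a
    deterministic simulator of phased, error-bearing spliced reads for
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    parallel,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    GenomicAlignments,
    optparse
Config/testthat/edition: 3
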