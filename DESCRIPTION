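Package: poolqtl
Title: Molecular QTL Mapping from Pooled Sequencing Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls molecular quantitative trait loci (QTLs) for transcription
    factor binding, chromatin accessibility, and chromosomal looping from
    pooled sequencing assays. Pool proportions are deconvolved from post-assay
    allele frequencies by simplex-constrained weighted least squares,
    pre-assay allele frequencies are predicted from genotypes, and each SNP is
    tested for a cis-acting allele-frequency shift with an exact binomial
    mid-p test. Includes an allele-swap remapping filter for reference mapping
    bias, allele-specific Hi-C contact extraction over chromatin loops,
    phased-haplotype linkage disequilibrium, GWAS lead-SNP window enrichment,
    allele-specific motif enrichment, loop-anchor QTL-to-gene assignment, and
    a seeded synthetic-data generator with known ground truth for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
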