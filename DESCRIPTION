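Package: orghap
Title: Organellar Haplotype Discovery from Multi-Sample VCFs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for maternal-lineage analysis of plant organellar genomes
    from multi-sample variant calls. Reads chloroplast and mitochondrial VCFs
    into a haploid-with-heterozygote genotype model, applies artifact filters
    (indel removal, population call-quality threshold, removal of sites
    heterozygous in multiple focal samples, a signature of nuclear-transferred
    organellar segments), selects population-wide or within-crop polymorphic
    SNP sets, computes pairwise identity matrices with pairwise-complete
    denominators, clusters samples into haplotype groups by single linkage on
    SNP difference counts, quantifies inter-haplotype divergence, builds
    neighbor-joining trees with column-bootstrap supports, and tabulates
    haplotypes against sample origin. A synthetic-data generator plants known
    haplotype structure and artifact processes so every stage can be tested
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
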