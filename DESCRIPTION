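Package: selmeta
Title: Composite Selection-Signature Scans by Meta-Analysis of Haplotype and Frequency Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects selective sweeps in phased SNP panels by combining four
    genome-scan statistics - the integrated haplotype score (iHS), the
    cross-population Rsb statistic, the between-population difference in
    derived allele frequency (dDAF), and a per-site observed-heterozygosity
    depression score (SHp) - into a single weighted Stouffer meta-statistic
    (meta-SS) per SNP and population, with Bonferroni thresholding. Includes
    marker and sample quality control (MAF, exact Hardy-Weinberg test, call
    rates, IBD relatedness pruning), ancestral-allele calling from pooled
    outgroup genotypes, extended-haplotype-homozygosity kernels written in
    C++, three gene-annotation strategies on user-supplied gene models, and a
    seeded synthetic-data generator with sweep injection for end-to-end
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
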