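Package: poolscan
Title: Pooled Resequencing Allele-Frequency Scans and Two-Locus Haplotype
    Association for Ascites Resistance in Broilers
Version: 0.1.0
Authors@R:
    person("Pool", "Scan", email = "maintainer@poolscan.dev", role = c("aut", "cre"))
Description: Tools for case-control pooled whole-genome resequencing
    (pool-seq) scans of the kind used to map ascites (pulmonary hypertension
    syndrome) resistance loci in broiler chickens. Implements per-SNP
    resistant-minus-susceptible allele-frequency differences from replicate
    DNA pools, depth and missingness filtering, gap-bounded clustering of
    skewed SNPs into candidate regions, per-genotype chi-square association
    with uncapped Bonferroni adjustment, a three-haplotype two-locus combined
    genotype model with allele-counting and EM haplotype frequency
    estimation, delta-delta-Ct relative expression analysis with Welch
    t-tests, and a penetrance-based synthetic data generator so that every
    stage of the pipeline can be exercised and validated without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Config/testthat/edition: 3
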