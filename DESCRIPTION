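Package: ldne
Title: Effective Population Size from Linkage Disequilibrium in SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates effective population size (Ne) from the decay of
    linkage disequilibrium in diploid SNP panels, as used for selfing crop
    germplasm. Provides VCF input/output for genotype dosage matrices,
    marker-level quality control (minor allele frequency, missingness,
    heterozygosity), windowed pairwise r2 and LD-decay summaries, per-SNP
    mean LD scores, physical-to-genetic distance conversion from cM/Mb
    ratios, and a two-stage least-squares estimator of Ne built on the
    Sved drift-recombination relation E(r2) = 1/(1 + 4*Ne*c). Includes a
    forward-time Wright-Fisher simulator with selfing and recombination
    for end-to-end parameter-recovery validation, and a pipeline driver
    that exports all intermediate tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
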