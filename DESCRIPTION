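Package: triotdt
Title: Trio-Based Transmission Disequilibrium Analysis for Targeted Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Family-based association analysis of targeted-sequencing data in
    child-parent trios. Implements a genotype quality-control cascade (depth,
    genotype quality, allele-balance, missingness, monomorphism), Mendelian
    inconsistency checking with a zero-out/drop policy, de novo variant
    detection under a strict missingness regime, the single-variant
    transmission disequilibrium test (TDT) with McNemar chi-square and odds
    ratios, a leave-one-out jackknife that partitions trios by the locus
    driving their signal, rare-variant collapsing TDTs (CMC, BRV, WSS, VT)
    with a within-family transmission-flipping permutation null, genotype
    frequency profiles of children versus parents, and a synthetic trio
    cohort generator with linkage-disequilibrium haplotype blocks,
    transmission-distorted risk loci, locus-heterogeneity subgroups,
    injected de novo variants, and planted quality-control failures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
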