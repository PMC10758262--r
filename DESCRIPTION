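Package: cLD
Title: Cumulative Linkage Disequilibrium Between Genomic Regions from Rare Variants
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes cumulative linkage disequilibrium (cLD), a region-level
    linkage-disequilibrium statistic for rare variants. Rare variants within a
    region (typically a gene) are collapsed into a per-haplotype carrier
    indicator, and the classical D, D' and r-squared disequilibrium statistics
    are evaluated on the resulting carrier frequencies (cumulative minor allele
    frequencies). Includes closed-form delta-method asymptotic variances of LD
    and cLD under a multinomial haplotype-table model, half-sample bootstrap
    stability assessment in cMAF bins, distance-stratified enrichment
    comparisons with Mantel-Haenszel and Fisher exact tests, case/control
    delta-cLD screening with hypergeometric gene-set enrichment, a forward-time
    Wright-Fisher simulator of cLD decay under recombination, selection and
    epistasis, phasing switch-error robustness experiments, and a synthetic
    phased-haplotype fixture generator. Phased haplotypes are read from VCF and
    regions from BED.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
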