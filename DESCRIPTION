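Package: hlafinemap
Title: Fine-Mapping of HLA Alleles, Amino Acids, Haplotypes, and KIR
    Compound Genotypes in Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Association analysis of classical HLA allele calls in
    case-control cohorts: covariate-adjusted additive logistic models for
    alleles and amino-acid residues, multi-allelic omnibus position tests,
    forward stepwise selection of independent effects with Bonferroni
    stopping rules, EM estimation of multi-locus haplotype frequencies from
    unphased genotypes, pairwise linkage-disequilibrium statistics, exact
    2x2 inference for carrier-level (dominant) analyses including the
    KIR3DS1 x HLA-B Bw4-80I compound genotype, imputation of the HLA-C
    3'UTR indel rs67384697 from classical alleles, fixed-effect
    cross-cohort heterogeneity (Cochran's Q, I-squared), and a synthetic
    cohort generator with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
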