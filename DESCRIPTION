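Package: resamplePRS
Title: Two-Stage Cross-Species Impulsivity Genetics with Polygenic Score
    Resampling and an Exact Combination Test
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for a two-stage translational genetics workflow linking
    rodent impulsivity to human phenotypes. The mouse arm computes
    five-choice serial reaction time task metrics, strain one-way ANOVA
    with narrow-sense heritability (between-strain over total sum of
    squares), and a strain-mean by expression Spearman screen gated by
    Benjamini-Hochberg false discovery rate. The human arm applies
    genotype quality control (call rate, minor allele frequency, exact
    Hardy-Weinberg test, sample missingness and heterozygosity, moment
    based identity-by-descent), sliding-window LD pruning, a repeated
    discovery/target polygenic score procedure with covariate-adjusted
    per-SNP regression and semi-partial correlations, and an exact
    combination test over resamplings that joins the count of positive
    correlations with the maximum one-sided p-value. SNP-set enrichment
    by gene-preserving permutation, univariate association, four-gamete
    haplotype-block construction with EM haplotype frequencies, and
    haplotype association tests are included, together with a synthetic
    data generator with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
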