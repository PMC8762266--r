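Package: admiximpute
Title: Ancestry-Stratified Genotype Imputation Accuracy in Admixed Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how reference-panel ancestry composition
    shapes genotype-imputation accuracy in recently admixed populations.
    Simulates three-way admixed cohorts (African, European, Native American)
    with exact local-ancestry tracts, emulates frequency-ascertained SNP
    genotyping arrays, imputes masked variants with a haplotype-copying
    hidden Markov model against phased reference panels, and evaluates
    dosage r-squared, INFO scores and counts of variants above GWAS quality
    thresholds, stratified by minor-allele frequency and local-ancestry
    diplotype. Includes an incremental-reference-panel experiment that
    projects how many genomes from an underrepresented ancestry are needed
    to close the imputation-accuracy gap.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    methods,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
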