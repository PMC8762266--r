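# admiximpute

Ancestry-stratified genotype-imputation accuracy in admixed cohorts.

## The problem

GWAS cohorts are genotyped on SNP arrays and imputed against phased
reference panels. In recently admixed populations — Latin American
cohorts above all — every genome is a mosaic of African (AFR), European
(EUR) and Native American (NAT) ancestry tracts, yet public reference
panels contain almost no Native American genomes and commercial arrays
were ascertained on European variation. The consequence is an accuracy
gradient *within* each genome: variants in NAT tracts are imputed worse
than variants in EUR tracts, and disease variants segregating on the
underrepresented background are systematically harder to detect.

`admiximpute` is for statistical geneticists who want to quantify that
gap and project how many reference genomes from the underrepresented
ancestry would close it. It provides, as composable R functions:

* a simulator for three differentiated source populations
  (Balding–Nichols allele frequencies over founder-mosaic haplotypes)
  and a single-pulse admixed cohort (proportions 1/6 AFR, 1/3 EUR,
  1/2 NAT, 12 generations ago by default) with exact truth ancestry
  tracts;
* an array designer that picks typed sites matching a target MAF
  spectrum in an ascertainment population and a target marker spacing,
  holding out all other sites as imputation truth;
* a haploid Li–Stephens copying HMM imputation engine: switch
  probability `1 − exp(−4·Ne·Δ/H)` between typed sites, mis-copy rate
  `λ`, forward–backward posteriors, linear-in-cM interpolation at
  untyped sites, genotype probabilities, dosages `P(Aa) + 2·P(aa)`,
  IMPUTE-style INFO scores, panel merging (intersect / cross-impute
  with hard calls) and leave-one-out driving;
* evaluation stratified by local-ancestry diplotype (`AFR_AFR` …
  `NAT_NAT`) and MAF class (common 0.5–0.05, low 0.05–0.01, rare
  0.01–0.003): pooled or per-individual dosage `r²` (minor-allele
  polarized), counts of variants above the GWAS quality threshold
  (MAF ≥ 0.01, INFO > 0.3) with paired *t* comparisons, the
  incremental-reference-panel experiment, and the gap analysis (added
  genomes needed for NAT_NAT accuracy to reach EUR_EUR).

VCF v4.2 (GT / GP / DS), tracks TSV, site lists, YAML configs and JSON
manifests are the interchange formats; see the methods vignette
(`vignettes/imputation-accuracy.Rmd`) for the models, parameter
defaults and design decisions.

## Worked example

The shipped desk-scale configuration (0.1 scale: base panel of 66 AFR +
50 EUR + 35 admixed individuals, 30 admixed targets, 6,000 sites on a
50 Mb chromosome, ~600-site EUR-ascertained array) runs in well under a
minute:

```r
library(admiximpute)
cfg <- desk_config(seed = 1, sizes = c(0L, 100L))
res <- run_experiment(cfg)
res$table[res$table$diplotype %in% c("EUR_EUR", "NAT_NAT") &
          res$table$bin %in% c("common", "rare"), ]
```

```
 added_ref_count diplotype    bin n_observations       r2 mean_info
               0   EUR_EUR common          10479 0.856729     0.725
               0   EUR_EUR   rare            250 0.490136     0.303
               0   NAT_NAT common          43828 0.626469     0.726
               0   NAT_NAT   rare           1025 0.000247     0.292
             100   EUR_EUR common          10479 0.853876     0.848
             100   EUR_EUR   rare            250 0.504881     0.365
             100   NAT_NAT common          43828 0.925356     0.853
             100   NAT_NAT   rare           1025 0.723387     0.338
```

Read: with no NAT reference genomes, common variants in NAT_NAT tracts
are imputed at r² = 0.63 versus 0.86 in EUR_EUR tracts, and rare-variant
carriers in NAT_NAT tracts are essentially never recovered (r² ≈ 0.0002
versus 0.49). Adding 100 NAT reference individuals lifts NAT_NAT to
0.93 (common) and 0.72 (rare) — the steepest gain is in the rare class —
while EUR_EUR accuracy is untouched (−0.003). `res$gap$gap` reports,
per MAF class, the smallest addition at which NAT_NAT reaches EUR_EUR;
`ancestry_fractions(res$world$target_tracks)$cohort_mean` confirms the
simulated cohort's ancestry proportions (0.129 / 0.311 / 0.560 for this
seed's 30 targets). `plot_accuracy_curves(res$table)` draws the
accuracy-versus-panel-size curves.

A thin CLI over the same functions is included for shell pipelines:

```sh
Rscript inst/scripts/pipeline.R experiment \
  --config inst/extdata/desk_scale_config.yaml --out out/
```

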