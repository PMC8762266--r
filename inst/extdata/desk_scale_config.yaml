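seed: 1
chromosome:
  length_bp: 50000000.0
  rate_cM_per_Mb: 1.0
n_sites: 6000
sources:
  AFR:
    divergence_F: 0.1
    n_founders: 40
    founder_switch_rate: 30.0
    mutation_flip_rate: 0.0001
  EUR:
    divergence_F: 0.12
    n_founders: 40
    founder_switch_rate: 30.0
    mutation_flip_rate: 0.0001
  NAT:
    divergence_F: 0.18
    n_founders: 40
    founder_switch_rate: 30.0
    mutation_flip_rate: 0.0001
donors_per_pop: 60
panel:
  n_afr: 66
  n_eur: 50
  n_admixed: 35
n_targets: 30
nat_pool: 100
admixture:
  afr: 0.166666666666667
  eur: 0.333333333333333
  nat: 0.5
  generations: 12
array:
  ascertainment_pop: EUR
  mean_spacing_bp: 83333
  histogram_proportions:
  - 0.1
  - 0.15
  - 0.2
  - 0.25
  - 0.3
ls:
  ne_eff: 10000.0
  lambda: 0.001
  min_switch: 1.0e-08
bins:
- 0.5
- 0.05
- 0.01
- 0.003
threshold:
  min_maf: 0.01
  min_info: 0.3
sizes:
- 0
- 20
- 50
- 100
r2_mode: pooled
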