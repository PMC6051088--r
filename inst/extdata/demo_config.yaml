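seed: 1
stages:
- simulate
- discover
- filter
- quantify
- normalize
- gate
- de
- survival
- targets
- enrich
sim:
  n_true_hairpins: 30
  n_decoy_loci: 20
  n_pairs: 30
  read_depth_per_locus: 50
  nb_dispersion: 0.1
  planted_log2fc:
  - 2.0
  - 2.0
  - 2.0
  - 2.0
  - 2.0
  - 2.0
  - -2.0
  - -2.0
  - -2.0
  - -2.0
  - -2.0
  - -2.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  hazard_ratio_high_vs_low: 3.0
  n_survival_loci: 2
  censor_rate: 0.3
  n_utrs: 200
  planted_sites_per_mirna: 3
  n_target_pool: 30
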