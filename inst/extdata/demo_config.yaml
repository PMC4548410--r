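# Demonstration pipeline configuration: three genotypes at one age,
# 50 pairs each, with small detector and tuning cohorts.
seed: 7
n_detect_pairs: 20
n_autapse_cells: 8
n_tuning_cells: 5
n_sim_reciprocity: 20000
mosaic:
  density_per_mm2: 300
  exclusion_radius_um: 30
cohorts:
  - genotype: Pcdhg22
    age_group: juvenile
    n_pairs: 50
  - genotype: Pcdhg0
    age_group: juvenile
    n_pairs: 50
  - genotype: Pcdhg1
    age_group: juvenile
    n_pairs: 50
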