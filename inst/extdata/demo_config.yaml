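# Demo configuration for the full seeded pipeline run at desk scale.
seed: 1
stages:
  simulate: true
  fracmetrics: true
  proteomics: true
  catalogues: true
  rna: true
windows:
  sec_fractions: [5, 6]
  lpp_density: [1.04, 1.07]
  ev_density: [1.09, 1.10]
sec:
  noise_cv: 0.1
  loss_fraction: 0.0
odg:
  noise_cv: 0.1
  loss_fraction: 0.0
proteomics:
  n_features: 300
  n_ev_markers: 20
  n_lpp_markers: 83
  n_corona: 10
  effect_log2: 3.0
  s0: 0.1
  min_valid_fraction: 0.6667
  n_permutations: 250
  fdr_alpha: 0.05
  imputation_width: 0.3
  imputation_downshift: 1.8
catalogues:
  alpha: 0.05
rna:
  n_mirna: 40
  n_permutations: 200
  library_size: 1.0e6
  dispersion: 0.1
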