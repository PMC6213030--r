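# Demo pipeline configuration: a reduced synthetic cohort so the full
# run finishes in a few seconds. Drop the `design:` block to use the
# full default study design (50 metabolites, 16384-point spectra,
# 200 permutations).
synthetic: true
n_components: 2
n_folds: 7
n_permutations: 50
network_threshold: 0.6
bin_alpha: 0.05
seed: 42
thresholds:
  p_threshold: 0.05
  fc_upper: 1.5
  fc_lower: 0.67
  normality_alpha: 0.05
  use_adjusted_p: false
design:
  n_terrestrial: 6
  n_marine: 18
  n_points: 4096
  seed: 42
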