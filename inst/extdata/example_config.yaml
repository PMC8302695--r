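# Example pipeline configuration. Every key is optional; unset keys take
# the package defaults (see ?pipeline_config).
seed: 1
min_abundance: 0.005      # core rule: mean relative abundance > 0.5%
min_occurrence: 0.5       # core rule: present in > 50% of samples
scope: both               # pool DNA + RNA samples for core selection
allow_within_tier: true
max_iter: 500
restarts: 0
prediction: parents       # CH4 prediction from gene/taxon evidence
community_prediction: joint
knockout_mode: retrain
scenario:
  n_samples: 24
  iht_effect: 0.8         # hydrogen-transfer path weight
  diet_effect: 0.2        # direct-electron-transfer path weight
  noise_sd: 0.2
  n_distractor_taxa: 3
extra_scenarios: []
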