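# Default run configuration: reproduces the headline cash-transfer analysis.
population:
  n_agents: 100000
  seed: 1
  cluster_weight: 0.7
  cluster_center: [12, 12]
  cluster_sd: 6
facilities:
  table: packaged
  locations: packaged
weights:
  g_mean: 1.0
  g_sd: 0.2
  d_mean: 0.05
  d_sd: 0.01
  l_mean: 3.0      # starting value; calibration refits this mean
  l_sd: 0.5
  a_home_mean: 0.0 # starting value; calibration refits this mean
  a_home_sd: 0.5
engine:
  batch_size: 20000
  n_runs: 50
  master_seed: 1
  money_form: capped_share
experiment:
  dose_from: 0
  dose_to: 1000000
  dose_by: 10000
  anchor_doses: [0, 280000]
  anchor_rates: [0.566, 0.300]
  tolerance: 0.015
  cal_runs: 10
  cal_agents: 5000
  sweep_runs: 10
  sweep_agents: 5000
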