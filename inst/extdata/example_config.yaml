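# Example pipeline configuration for the command-line wrapper
# (inst/cli/pdzmodes.R). With `synthetic: true` the built-in Markov
# generator supplies the trajectory; point `trajectory:` at a multi-model
# PDB plus topology TSV to analyse real data instead.
output_dir: pdzmodes_out
seed: 1
trajectory:
  synthetic: true
  n_frames: 20000
  jitter_sigma: 0.15
  dt_ps: 1
cutoffs:
  hbond_dist: 3.6
  hbond_angle_deg: 30
  ionic: 5
  leader_rmsd: 2
  burn_in_ns: 0
  rmsf_window_ns: .inf
rmsf:
  chain: P
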