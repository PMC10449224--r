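# Small demonstration scenario grid for run_experiment() / the simulate CLI.
# Sizes are deliberately tiny so the grid finishes in seconds; see the
# package vignette for the full-scale and desk-scale study configurations.
genome:
  length_bp: 1.0e+06
  exon_fraction: 0.015
  mean_exon_len: 160
  mean_recomb_rate: 1.0e-08
  n_rate_pieces: 10
  seed: 3
dfe:
  shape_k: 0.186
  scale_theta: 0.07068995
  mutation_rate: 1.5e-08
sim:
  N_recipient: 500
  N_source: 50
  isolation_generations: 100
  post_pulse_generations: 100
  pulse_fraction: 0.05
  recipient_female_fraction: 0.5
  scaling_factor: 1
  pulse_mode: exact
grid:
  inheritance: [autosomal, chrX]
  dominance_h: [0.0, 0.5]
  female_fraction_pulse: [0.0, 0.5, 1.0]
sampling:
  sample_size: 100
  schedule: [1, 10, 20, 40, 100]
analysis:
  n_boot: 200
  n_per_draw: 1000
seed: 42
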