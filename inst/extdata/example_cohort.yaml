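# Demonstration cohort specification for the synth-cohort CLI subcommand.
# Planted group-level per-bp archaic coverage rates; aut:chrX ratios 6.1
# and 4.3.
groups:
  - group: EURAMRlike
    n_individuals: 12
    aut_rate: 0.021
    chrx_rate: 0.0034426
  - group: SASEASlike
    n_individuals: 12
    aut_rate: 0.026
    chrx_rate: 0.0060465
mean_tract_len: 5.0e+04
posterior_below_frac: 0.1
snp_zero_prob: 0.3
seed: 7
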