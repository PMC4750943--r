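# Nutrient condition III (hypernourished): glucose 25 mM, oxygen 0.28 mM.
# Desk-scale defaults; the reference experiments start from ~10000 cells
# and run for 48 days.
condition: "III"
variant: 4
n_initial: 800
t_end: 216
dt_field: 1.0
output_every: 12
grid_factor: 2
lattice:
  n_per_dim: 34
  spacing: 16.8
  jitter: 0.25
seed: 7
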