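# One point of the supercoiling x crowding grid, desk scale.
# delta_lk: integer linking deficit, or "nicked" for a torsionally
# unconstrained molecule.
delta_lk: -7
phi: 0.05
n_beads: 334
m_rings: 4
sampler: bd
n_steps: 200000
sample_every: 1000
seed: 1
analyses: [shape, topology]
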