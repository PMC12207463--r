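name: layout/eight_cell_6v2
layout: eight_cell
mixed_ratio: [6, 2]
preset: micro
n_episodes: 150
probe_every: 1500
seed: 1
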