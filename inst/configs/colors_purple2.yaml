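name: colors/purple2_6v2
layout: default
mixed_ratio: [6, 2]
color_pair: purple2
preset: micro
n_episodes: 150
probe_every: 1500
seed: 1
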