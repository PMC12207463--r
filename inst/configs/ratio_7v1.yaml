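name: ratio_sweep/7v1
layout: default
mixed_ratio: [7, 1]
color_pair: default
preset: micro
n_episodes: 150
probe_every: 1500
probe_episodes: 4
probe_max_steps: 200
seed: 1
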