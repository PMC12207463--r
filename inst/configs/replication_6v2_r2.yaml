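name: ratio_sweep/6v2
layout: default
mixed_ratio: [6, 2]
preset: micro
n_episodes: 150
probe_every: 1500
replication: 2
seed: 2
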