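name: individuation/dark_7v1
layout: default
mixed_ratio: [7, 1]
individuation: yes
pixel_variant: dark
elevated_freeze: 64
preset: micro
n_episodes: 150
probe_every: 1500
seed: 1
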