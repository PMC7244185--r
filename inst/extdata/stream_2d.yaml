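# Dense 2D stream-prone setting: strong repulsion, weak steering
preset: table2
N: 2000
T: 1000
record_every: 50
seed: 3
init_mode: random
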