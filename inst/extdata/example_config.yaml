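# Minimal C+L+M interface experiment (prepared stripes)
variant: minimal_CLM
alpha: 0.5
beta: 0.5
gamma: 1.5
K: 0.5
L: 150
max_mcs: 1000
sample_every: 2
relaxation_mcs: 800
seed: 1
replicates: 10
init:
  mode: blocks
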