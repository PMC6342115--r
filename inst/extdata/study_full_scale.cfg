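# Full-scale simulation study (long-running: hours on one CPU)
nx = 100
ny = 100
replicates = 100
n = 100
b = 1
family = gamma
range = 20
sigma2 = 1
draws = 1000
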