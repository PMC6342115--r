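# Scaled simulation study: finishes in minutes on one CPU
nx = 32
ny = 32
replicates = 30
n = 100
b = 1
family = gamma
range = 6.4
sigma2 = 1
draws = 1000
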