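alpha: 0.05
qcVariabilityFraction: 0.01
monomorphicEpsilon: 0.02
sdDnullMethod: binned_smoothed
binSize: 1000
regionMaxGap: 1000000
regionMinSnps: 3
annotationWindow: 1000000
seed: 1
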