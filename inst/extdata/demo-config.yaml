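# Reduced-size demo configuration: every stage of the synthetic pipeline on
# two duplex conditions. Remove keys to fall back to the package defaults.
seed: 1
traces:
  conditions: ["oxoG/C", "oxoG/oxoG-clamp"]
  n_points: 150
selection:
  enabled: false
fit:
  n_starts: 3
melting:
  duplexes: ["oxoG/C", "oxoG/oxoG-clamp", "G/C", "G/oxoG-clamp"]
cleavage:
  conditions: ["oxoG/C", "oxoG/oxoG-clamp"]
  n_points: 10
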