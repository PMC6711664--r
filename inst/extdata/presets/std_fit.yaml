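# Reduced short-term-depression model of the maximal response.
model: std
tau_rate: 5
tau_recover: 200
reference_fit:
  fg_strength: 2.56
  depletion_strength: 0.125
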