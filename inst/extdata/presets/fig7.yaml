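# Two mutually inhibitory familiar-stimulus populations.
model: competition
mutual_inhibition: 0.1
transfer_threshold: -3
fgbar_R: 0.9
adapt_strength: 1.8
tau_rate: 5
tau_adapt: 200
drive:
  amp_slow: 1
  amp_fast: 1
  tau_slow: 400
  tau_fast: 20
  offset: 0
onset_gap: 500
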