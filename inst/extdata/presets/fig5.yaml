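# Mean-field fit to the dimming-detection responses.
model: meanfield
recurrent_scale: 0
adapt_strength: 1.8
tau_rate: 5
tau_adapt: 200
fgbar_R: 0.9
fbar_R: 0.3
fbar_F: -0.7
fgbar_F: 0
drive_mean:
  amp_slow: 6
  amp_fast: 5
  tau_slow: 700
  tau_fast: 40
  offset: -1
drive_m:
  amp_slow: 5
  amp_fast: 5
  tau_slow: 400
  tau_fast: 20
  offset: 0
successive:
  present_ms: 150
  decay: exponential
  tau_decay: 50
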