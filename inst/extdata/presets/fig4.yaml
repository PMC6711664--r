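# Example-network protocol: Hebbian recurrent plasticity + uniform
# feedforward depression + firing-rate adaptation.
model: network
n_units: 2000
recurrent_scale: 0
adapt_strength: 1.8
tau_rate: 5
tau_adapt: 200
drive:
  amp_slow: 1
  amp_fast: 1
  tau_slow: 150
  tau_fast: 50
  offset: 0
present_ms: 150
decay_ms: 100
decay: linear
xi_shape: 3
hebbian_strength: 0.9
feedforward_gain_learned: 0.4
baseline_rate: 5
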