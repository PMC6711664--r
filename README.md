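# famdyn

Visual responses in primate inferior temporal cortex (ITC) *sharpen* with
familiarity: after an image has been learned, the average population response
drops, the response to the preferred stimulus grows, and the time course
acquires a damped ~5 Hz oscillation with a characteristic rebound ~230–320 ms
after stimulus onset. `famdyn` implements a rate-network account of these
changes — separable synaptic plasticity interacting with firing-rate
adaptation — together with the analysis pipeline that infers the plasticity
rule back from rank-ordered response time courses. It is aimed at
computational neuroscientists modelling learning-related changes in cortical
dynamics, and at experimentalists who want to apply the inference pipeline to
their own rank × time response matrices.

## The model

Firing rates follow a standard rate equation with adaptation,

    tau_r dr_i/dt = -r_i + Phi( sum_j W^R_ij r_j - k a_i + I_i(t) )
    tau_a da_i/dt = -a_i + r_i ,

where `Phi` is the static f–I curve, `a_i` a low-pass filtered copy of the
rate (strength `k`, time constant `tau_a`), and learning applies a one-shot
separable update `dW^R_ij = f_R(xi_i) g_R(xi_j) / N` (plus feedforward
depression `f_F`). With linear `Phi` and zero-sum `g_R`, the network reduces
exactly to four mean-field variables: the population mean rate and adaptation
(`rbar`, `abar`) and the overlap with the learned pattern and its adaptation
(`m`, `n`). The learned (m, n) block is governed by the 2 × 2 matrix

    [ (fg_R - 1)/tau_R   -k/tau_R  ]
    [ 1/tau_A            -1/tau_A  ]

whose eigenvalues classify the response as a stable node (monotone decay,
novel stimuli) or a stable focus (damped oscillation, familiar stimuli) with
period `2*pi / Im(lambda)`. At the fitted parameters (`fg_R = 0.9`,
`k = 1.8`, `tau_R = 5` ms, `tau_A = 200` ms) the period is ~150 ms.

The inference pipeline runs the model backwards on the 5 ms data grid
(`tau_r = dt`): external inputs are reconstructed exactly from novel
responses, `I_i(t) = Phi^-1(r_i(t+dt)) + k a_i(t)`, and each rank's familiar
response then yields a two-parameter weighted least-squares problem for the
post-synaptic plasticity dependences `f_R(i)` (recurrent) and `f_F(i)`
(feedforward), with the measured top-rank familiar trace as the regressor
(teacher forcing).

## Worked example

```r
library(famdyn)

# 1. Regime of the learned overlap dynamics at the fitted parameters
classify_regime(feedback = 0.9, k = 1.8, tau_rate = 5, tau_adapt = 200)
#> Regime of the 2-variable linear block
#>   feedback w = 0.9, k = 1.8, tau_R = 5 ms, tau_A = 200 ms
#>   eigenvalues: -0.0125 +0.041758i, -0.0125 -0.041758i (1/ms)
#>   discriminant: -0.006975 (1/ms^2)
#>   label: stable_focus
#>   damped-oscillation period: 150.5 ms

# 2. Generate a passive-viewing surrogate (125 ranks x 44 bins, 5 ms) with
#    known ground truth and recover the plasticity rule from it
dat <- synthesize_dataset(noise_sd = 0.1, seed = 7)
fit <- fit_plasticity(dat$novel, dat$familiar)
summary(fit)
#> Summary of plasticity-dependence fit
#>   ranks: 125, bins: 44
#>   mean f_R: 0.3094   mean f_F: -0.7008   top-rank f_R: 0.8956
#>   Spearman rho(f_R, rank): 0.999
#>   total weighted SSE: 256.308
```

The recovered rule is what the theory predicts from the data: recurrent
potentiation increasing with stimulus rank (mean ≈ 0.3, ≈ 0.9 at the
preferred stimulus — strong positive feedback in the high-rate assembly) and
uniform feedforward depression (mean ≈ −0.7), which together produce the
sharper, oscillatory familiar response. On a longer surrogate the rebound
statistic shows the rank-graded pattern seen in recordings:

```r
dat70 <- synthesize_dataset(n_bins = 70, noise_sd = 0.1, seed = 7)
round(rebound_strength(dat70$familiar)[c(1, 63, 125)], 4)
#> [1] 0.0009 0.0133 0.0257      # slope (rate units/ms), bottom/middle/top rank
```

Other entry points: `simulate_network()` / `preset_network()` (full network,
e.g. the 2000-unit Hebbian example), `preset_meanfield()` +
`simulate_meanfield()` (fitted mean-field model, single or successive
presentations), `simulate_competition()` (two mutually inhibitory familiar
populations), `simulate_global_inhibition()` and `simulate_std_reduced()` /
`fit_std()` (alternative negative-feedback models), `normalize_and_rank()`
and `read_rank_time_csv()` (data-facing I/O), `derive_transfer()` (nonlinear
f–I curve from novel responses by quantile matching).

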