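---
title: "Models and inference for familiarity-sharpened response dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and inference for familiarity-sharpened response dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famdyn)
```

## The scientific problem

When a monkey learns a visual stimulus, inferior temporal cortex (ITC)
responds to it differently: the population-average response decreases, the
response to the most preferred stimulus increases, and the time course
changes qualitatively — novel stimuli evoke a transient that decays
monotonically, familiar stimuli evoke a damped oscillation whose rebound
(~230–320 ms after onset) grows with the stimulus' rank in the neuron's
tuning. `famdyn` implements a mechanistic account of these observations and
the inference machinery it licenses.

The core hypothesis is an interaction of two ingredients:

1. **Separable synaptic plasticity.** A one-shot update
   $\Delta W^R_{ij} = f_R(\xi_i)\,g_R(\xi_j)/N$ of the recurrent weights
   (and a feedforward counterpart with dependence $f_F$), where $\xi_i$ is
   the unit's time-averaged response to the learned stimulus. Potentiation
   concentrated among high-rate units strengthens positive feedback in the
   learned assembly; depression of feedforward inputs lowers the average
   drive.
2. **Firing-rate adaptation.** A slow, private negative feedback: each
   unit's input is reduced by $k\,a_i$, where $a_i$ low-pass filters $r_i$
   with time constant $\tau_A$.

Neither ingredient alone reproduces the data: plasticity without slow
negative feedback changes response amplitudes but not their temporal shape,
and adaptation without learned positive feedback produces at most an
overshoot, never a growing oscillation.

## Mean-field reduction and regime analysis

With a linear transfer function and zero-sum pre-synaptic dependence
($\sum_j g_R(\xi_j) = 0$, weight-sum conservation), averaging the network
equations gives an exact four-variable system in the population mean rate
and adaptation $(\bar r, \bar a)$ and the learned-pattern overlap and its
adaptation $(m, n)$. The package integrates this system (`simulate_meanfield()`)
with explicit Euler; the reduction is exact at the discrete level too, which
is what the network/mean-field equivalence test checks at $10^{-6}$ relative
tolerance (it holds to machine precision).

The $(m, n)$ block is linear with system matrix
$\begin{pmatrix}(\overline{fg}_R - 1)/\tau_R & -k/\tau_R\\ 1/\tau_A &
-1/\tau_A\end{pmatrix}$. `classify_regime()` reports its eigenvalues,
discriminant, and regime label:

* **stable node** (real eigenvalues) — monotone/overshoot decay, the
  pre-learning regime;
* **stable focus** (complex pair) — damped oscillation with period
  $2\pi/\mathrm{Im}\,\lambda$, the post-learning regime;
* **unstable** — beyond $\overline{fg}_R \ge 1 + \tau_R/\tau_A$ or
  $\overline{fg}_R - k - 1 \ge 0$.

```{r}
classify_regime(feedback = 0.9, k = 1.8, tau_rate = 5, tau_adapt = 200)
```

Boundary cases (zero discriminant, zero real part) are labelled by closed-set
convention (node / stable); the raw discriminant and eigenvalues are returned
so callers can apply their own tolerance. The node/focus separatrix is the
parabola $k_{sep}(w) = \tfrac{\tau_R\tau_A}{4}\left(\tfrac{w-1}{\tau_R} +
\tfrac{1}{\tau_A}\right)^2$ (`separatrix_k()`, `phase_diagram()`).

Two further pre-learning constraints are implemented: no oscillation before
learning (positive discriminant at feedback $w_R$) and suppression of the
second peak under successive novel presentations. The latter uses the
piecewise-linear approximation of the two-pulse protocol
(`second_peak_condition()`): the rate rises linearly to $r_0$ over $t_0$
under constant input $I_0 = r_0\tau_{eff}/t_0$ with
$\tau_{eff} = \tau_R/(1-w_R)$, decays linearly to $r_1$ over $t_1$ while the
adaptation integrates to a closed-form $a_1$, and the second peak is
$(I_0 - a_1 k)\,t_0/\tau_{eff} + r_1$. (A published rendering of this
expression drops one $1/\tau_{eff}$ factor; the package implements the
dimensionally consistent form, which also follows from the stated
substitution $r_0 = I_0 t_0/\tau_{eff}$. Likewise the eigenvalue formula is
used in its standard $(\mathrm{tr}\pm\sqrt{\mathrm{disc}})/2$ form.)

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `tau_rate` | rate time constant | 5 ms | fitted value; also the data bin width |
| `tau_adapt` | adaptation time constant | 200 ms | fitted value, consistent with cellular adaptation |
| `adapt_strength` (k) | adaptation gain | 1.8 | fitted value |
| `recurrent_scale` (w_R) | pre-learning feedback | 0 | fitted value (effective E−EI/IE coupling; may be negative) |
| `fgbar_R` | learned positive feedback | 0.9 | fitted value; stable focus with ~150 ms period |
| `fbar_R`, `fbar_F` | mean post-synaptic dependences | 0.3, −0.7 | fitted values: net recurrent potentiation, feedforward depression |
| `dt` (simulation) | Euler step | 0.5 ms | ≤ τ_R/10; halving changes trajectories at first order only |
| `dt` (inference) | data grid | 5 ms | recording bin width; with τ_R = dt the discrete update inverts exactly |

Drive waveforms are differences of two exponentials
$a e^{-t/\tau_s} - b e^{-t/\tau_f} + c$ with the offset convention
$c = b - a$ (zero at onset). The fitted presets (`load_preset()`,
`preset_meanfield()`, `preset_competition()`, `preset_network()`) carry the
published parameter sets; field names (`amp_slow`, `tau_slow`, …) replace
the overloaded printed symbols, and the two distinct quantities both printed
as "gamma" (feedforward gain 0.4 vs depression strength 0.125) live in
different types so they cannot collide.

## The inference pipeline

On the 5 ms data grid the package sets $\tau_r = dt$, so the discrete update
reads $r_i(t+dt) = \Phi(w_R\bar r(t) - k a_i(t) + I_i(t))$ and inverts
exactly: `reconstruct_input()` recovers $I_i(t)$ from novel responses alone,
and the forward model run on the reconstructed input reproduces the novel
matrix to machine precision. `fit_plasticity()` then solves, per rank, the
two-parameter weighted least-squares problem

$$\Phi^{-1}(r_i^{fam}(t+dt)) - w_R\bar r^{fam}(t) + k a_i^{fam}(t) - I_i(t)
 = f_{R,i}\, r^{fam}_{max}(t) + f_{F,i}\, I_{max}(t),$$

with the pre-synaptic dependence taken as one-hot on the top rank (so the
overlap *is* the preferred-stimulus trace; this convention drops the 1/N of
the mean-field module, the constant being absorbed in the fitted
coefficients). The measured top-rank familiar trace is used as the regressor
(teacher forcing) so errors in fitting the top rank do not propagate. Late
bins (≥ 230 ms) receive weight 5 to capture the rebound; on a noise-free
consistent system the weights are irrelevant and recovery is exact, which the
tests assert at $10^{-8}$.

Degenerate designs (top-rank trace proportional to its input, e.g. constant
traces) are detected by rank deficiency and reported with `NA` coefficients
rather than arbitrary estimates.

`derive_transfer()` recovers a nonlinear f–I curve from the time-averaged
novel responses (75–200 ms window) by quantile matching against standard
normal inputs, using plotting positions $(i - 0.5)/n$ (the Gaussian's mean
and scale are not identifiable and are absorbed into the table), followed by
isotonic cleanup; inversion uses monotone piecewise-linear interpolation with
linear extrapolation beyond the table, flagged via an attribute.

`rebound_strength()` is the ordinary least-squares slope over 230–320 ms.
The "+2" offset sometimes used to display normalized rates on logarithmic
axes is plotting-only and appears nowhere in computation.

## Alternative negative-feedback models

* **Global inhibition** (`simulate_global_inhibition()`): the slow variable
  filters the population mean instead of each unit's own rate; the overlap
  equation becomes first-order and cannot oscillate — the package asserts
  this (no local maximum after the first peak) under the fitted drive shapes.
* **Short-term synaptic depression** (`simulate_std_reduced()`,
  `simulate_std_network()`, `fit_std()`): presynaptic resources
  $x_j \in (0,1]$ deplete at rate $\gamma x_j r_j$ and recover with
  $\tau_x = 200$ ms. The reduced two-variable model of the high-rate
  population is fitted to maximal-response traces by a deterministic
  60 × 60 log-spaced grid search over $(\overline{fg}, \gamma)$ followed by
  Nelder–Mead refinement in log space (the input is obtained from the novel
  trace via the model's own pre-learning equation). At its best-fit
  parameters the model produces no rebound after the global peak — depression
  is too tied to the instantaneous rate to act as the required *private,
  delayed* negative feedback.
* **Competition** (`simulate_competition()`): two mutually inhibitory
  populations, each following the single-stimulus overlap dynamics, with the
  piecewise-linear transfer $\Phi(x) = x$ for $x \ge -3$ (implemented
  literally, including its negative outputs on $(-3, 0)$). The second
  population is frozen at zero before its onset ("silent" is not given a
  mechanism in the source account; freezing is the minimal reading). After
  the second stimulus arrives, the first population is transiently suppressed
  and then oscillates more strongly at a similar frequency — both populations
  start from 0, as no common baseline offset is specified.

## Numerical choices

* Explicit Euler with `dt = 0.5` ms for all continuous-time simulation;
  trajectories converge at first order (tested by step halving against a
  fine-step reference). Instabilities abort with the first bad time step
  named.
* The resource equation is advanced by exponential Euler (exact for the
  step-frozen rate). The explicit update is unstable on the 5 ms data grid
  whenever $\gamma r\,dt > 2$ — true at the best-fit depression strength —
  while the exponential step is unconditionally stable and preserves
  $x \in (0,1]$.
* Negative rates are permitted under the linear transfer (the linear theory
  requires them; normalized units are signed anyway); `clip_rates` exists but
  defaults off.
* Rank ties in `normalize_and_rank()` are broken by first occurrence
  (stable order).
* The discrete forward model on the data grid is explicit in time —
  $r(t+dt)$ depends only on states at $t$ — so the self-driven top-rank
  familiar trace is generated by direct recursion; no implicit solve arises.
* In the successive-presentation comparison, peak sizes are measured as the
  rise above the immediately preceding trough (for the first peak, the
  pre-onset baseline). Raw peak heights conflate the oscillation with the
  plasticity-driven boost of the familiar first transient; the
  trough-referenced measure isolates the recovery of the second response,
  which is the phenomenon of interest (the adaptation carried into the second
  onset is less than half as large after learning).

## The synthetic-data generator

`synthesize_dataset()` emulates the passive-viewing layout: 125 rank-ordered
stimuli × 44 bins at 5 ms in normalized (z-score-like) units. Per-rank
double-exponential drives ($\tau_{slow} = 150$ ms, $\tau_{fast} = 50$ ms)
have amplitudes spread along normal quantiles (mean 5, sd 2), matching the
Gaussian-input assumption of the transfer-function derivation; the drive
starts at 80 ms, the response latency the recordings themselves encode by
starting their normalization window there. Ground-truth dependences default
to the fitted mean-field coefficients ($f_R$ ramping −0.3 → 0.9, mean 0.3;
$f_F$ ramping −0.9 → −0.5, mean −0.7). Observation noise is iid Gaussian,
added after the dynamics — the emulated quantities are trial-averaged rates,
so dynamical noise is deliberately absent. Identical seeds give bitwise
identical datasets.

What passing tests on surrogates do and do not show: they establish that the
pipeline inverts the model class correctly (exact recovery when the data obey
the model; graceful, monotone degradation under observation noise; preserved
rank ordering at realistic noise), not that ITC data obey the model. Real
recordings have trial-to-trial variability, rank ties, non-Gaussian noise and
model mismatch that the surrogate deliberately omits.

A consequence worth stating plainly: the published best-fit depression
parameters ($\overline{fg} = 2.56$, $\gamma = 0.125$) characterize the actual
recorded maximal-response traces, which are distributed as supplements of the
original article and are not redistributable here.
`synthetic_reference_max_traces()` provides a labelled synthetic stand-in
with the right structure, and `fit_std()` is verified by exact
self-consistency recovery on its own forward model; but the stand-in's
best-fit values differ from the published ones (the depletion strength, in
particular, scales inversely with the data's rate scale), so the
corresponding acceptance assertion documents a data dependency rather than a
reproducible computation, and is expected to fail without the original
traces.

## Problem sizes

The shipped tests and the acceptance script run, by design, at the sizes the
analyses themselves use: the full 125 × 44 inference layout, a 500-unit
network for the mean-field equivalence check, the 2000-unit example network
for one protocol run, 200 random parameter draws for the regime-vs-simulation
property, and ~100 draws for the second-peak oracle. The whole suite
completes in about a minute on one core.

## Known limitations

* Linearity is load-bearing for the exactness results; with a tabulated
  transfer the reconstruction is exact only within the table's invertible
  range (extrapolation is linear and flagged).
* Only post-synaptic dependences are identifiable from single-cell data; the
  pre-synaptic dependence is assumed one-hot on the top rank for inference.
* One-shot learning only: no online plasticity during a trial.
* No spiking, no conductances, no stochastic integration, at most two
  competing populations, and no inhibitory-population modelling beyond the
  instantaneous-inhibition assumption folded into `recurrent_scale`.
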