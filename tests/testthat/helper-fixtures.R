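# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# Small noise-free surrogate for fast inference tests.
small_surrogate <- function(n_ranks = 20, n_bins = 30, noise_sd = 0,
                            seed = 42, ...) {
  synthesize_dataset(n_ranks = n_ranks, n_bins = n_bins,
                     truth_f_R = seq(-0.3, 0.9, length.out = n_ranks),
                     truth_f_F = seq(-0.9, -0.5, length.out = n_ranks),
                     noise_sd = noise_sd, seed = seed, ...)
}

# Euler low-pass of a trace, independent reimplementation for oracles.
lowpass_trace <- function(r, dt, tau) {
  a <- numeric(length(r))
  a[1] <- r[1]
  for (t in seq_len(length(r) - 1)) a[t + 1] <- a[t] + dt / tau * (r[t] - a[t])
  a
}
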