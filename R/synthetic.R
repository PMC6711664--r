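#' Sample stimulus selectivities from a gamma distribution
#'
#' Per-unit selectivity amplitudes \eqn{\xi_i} are gamma-distributed with
#' shape 3 (unit scale by default), matching the skewed, strictly positive
#' tuning amplitudes used in the example network.
#'
#' @param n_units number of draws.
#' @param shape gamma shape parameter.
#' @param scale gamma scale parameter.
#' @param seed optional RNG seed for reproducibility.
#' @return numeric vector of positive selectivities.
#' @export
sample_selectivity <- function(n_units, shape = 3, scale = 1, seed = NULL) {
  stopifnot(n_units >= 1, shape > 0, scale > 0)
  if (!is.null(seed)) set.seed(seed)
  stats::rgamma(n_units, shape = shape, scale = scale)
}

#' Generate a surrogate passive-viewing dataset
#'
#' Emulates the structure of the rank-averaged passive-viewing recordings: a
#' novel and a familiar rank x time matrix (default 125 ranks x 44 bins at
#' 5 ms), produced by the same discrete forward model the inference pipeline
#' inverts, with known ground-truth post-synaptic plasticity dependences and
#' iid Gaussian observation noise added last.
#'
#' Each rank receives a double-exponential input whose amplitude increases
#' with rank along normal quantiles (so the time-averaged novel responses have
#' the Gaussian-like spread the transfer-function derivation assumes). The
#' familiar matrix adds the learned terms \eqn{f_R(i)\, r^{fam}_{max}(t)} and
#' \eqn{f_F(i)\, I_{max}(t)} with a one-hot pre-dependence on the top rank;
#' the top-rank trace drives itself by direct recursion (the forward update is
#' explicit in time).
#'
#' Default truth vectors follow the fitted mean-field coefficients: f_R ramps
#' linearly from -0.3 to 0.9 across ranks (mean 0.3, top-rank value 0.9) and
#' f_F from -0.9 to -0.5 (mean -0.7).
#'
#' @param n_ranks,n_bins layout (default 125 x 44).
#' @param dt bin width in ms.
#' @param truth_f_R,truth_f_F ground-truth per-rank dependences (length
#'   `n_ranks`).
#' @param transfer a `"transfer_fun"` used by the forward model.
#' @param drive list with fields `mu`, `sigma` (amplitude mean and spread
#'   across ranks), `tau_slow`, `tau_fast` (ms), `onset` (ms; the visual
#'   response latency of inferotemporal neurons, so the surrogate's peak,
#'   trough and rebound fall at data-like times), `baseline`.
#' @param k adaptation strength.
#' @param tau_adapt adaptation time constant in ms.
#' @param w_R pre-learning recurrent strength.
#' @param noise_sd observation noise sd (rate units), added after dynamics.
#' @param seed optional RNG seed; identical seeds give identical datasets.
#' @return object of class `"surrogate_dataset"`: list with `novel`,
#'   `familiar` (`"rank_time_matrix"`), `truth_f_R`, `truth_f_F`, `inputs`,
#'   `transfer`, `noise_sd`, `seed`.
#' @export
synthesize_dataset <- function(n_ranks = 125, n_bins = 44, dt = 5,
                               truth_f_R = seq(-0.3, 0.9,
                                               length.out = n_ranks),
                               truth_f_F = seq(-0.9, -0.5,
                                               length.out = n_ranks),
                               transfer = linear_transfer(),
                               drive = list(mu = 5, sigma = 2,
                                            tau_slow = 150, tau_fast = 50,
                                            onset = 80, baseline = 0),
                               k = 1.8, tau_adapt = 200, w_R = 0,
                               noise_sd = 0, seed = NULL) {
  stopifnot(length(truth_f_R) == n_ranks, length(truth_f_F) == n_ranks,
            n_bins >= 3L, dt > 0)
  if (!is.null(seed)) set.seed(seed)
  tm <- (seq_len(n_bins) - 1L) * dt
  amp <- drive$mu + drive$sigma * stats::qnorm((seq_len(n_ranks) - 0.5) /
                                                 n_ranks)
  onset <- if (is.null(drive$onset)) 0 else drive$onset
  wave <- drive_value(drive_waveform(1, 1, drive$tau_slow, drive$tau_fast,
                                     offset = 0, onset = onset), tm)
  inputs <- drive$baseline + outer(amp, wave[-n_bins])   # ranks x (T-1)

  nov <- .forward_discrete(inputs, n_bins, dt, transfer, k = k,
                           tau_adapt = tau_adapt, w_R = w_R)$rates
  fam <- .forward_discrete(inputs, n_bins, dt, transfer, k = k,
                           tau_adapt = tau_adapt, w_R = w_R,
                           f_R = truth_f_R, f_F = truth_f_F)$rates
  if (noise_sd > 0) {
    nov <- nov + stats::rnorm(length(nov), sd = noise_sd)
    fam <- fam + stats::rnorm(length(fam), sd = noise_sd)
  }
  structure(list(
    novel = rank_time_matrix(nov, dt = dt, condition = "novel"),
    familiar = rank_time_matrix(fam, dt = dt, condition = "familiar"),
    truth_f_R = truth_f_R, truth_f_F = truth_f_F,
    inputs = inputs, transfer = transfer, noise_sd = noise_sd, seed = seed),
    class = "surrogate_dataset")
}

#' @export
print.surrogate_dataset <- function(x, ...) {
  cat(sprintf("Surrogate passive-viewing dataset: %d ranks x %d bins (dt = %g ms)\n",
              nrow(x$novel), ncol(x$novel), attr(x$novel, "dt")))
  cat(sprintf("  noise sd: %g; truth f_R in [%.3g, %.3g], f_F in [%.3g, %.3g]\n",
              x$noise_sd, min(x$truth_f_R), max(x$truth_f_R),
              min(x$truth_f_F), max(x$truth_f_F)))
  invisible(x)
}

#' Synthetic stand-in for the passive-viewing maximal-response traces
#'
#' The published maximal-response time courses (preferred-stimulus responses
#' before and after learning) are distributed as binary supplements of the
#' original article and are not shipped here. This function returns a clearly
#' synthetic substitute with the same structure — z-scale units, 5 ms bins,
#' covering the rebound window — namely the top-rank novel and familiar traces
#' of the package's passive-viewing surrogate ([synthesize_dataset()]) at its
#' default, noise-free study conditions (top-rank recurrent potentiation 0.9,
#' adaptation k = 1.8, tau_A = 200 ms).
#'
#' @param n_bins number of 5 ms bins (default 70, covering 0-345 ms so the
#'   rebound window is included).
#' @param dt data-grid bin width in ms.
#' @return list with `novel_max` and `familiar_max` (numeric traces) and
#'   `times` (ms).
#' @export
synthetic_reference_max_traces <- function(n_bins = 70, dt = 5) {
  d <- synthesize_dataset(n_bins = n_bins, dt = dt, noise_sd = 0)
  n <- nrow(d$novel)
  list(novel_max = as.numeric(unclass(d$novel)[n, ]),
       familiar_max = as.numeric(unclass(d$familiar)[n, ]),
       times = (seq_len(n_bins) - 1L) * dt)
}
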