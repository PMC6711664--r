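#' Load a shipped parameter preset
#'
#' Presets are data files (YAML) carrying the published parameter sets:
#' `"fig4"` (example network: Hebbian recurrent plasticity, feedforward
#' depression, adaptation), `"fig5"` (mean-field fit to the dimming-detection
#' responses, including the successive-presentation protocol), `"fig7"`
#' (two-population competition), and `"std_fit"` (reduced
#' short-term-depression model).
#'
#' @param name preset name.
#' @return named list of parameters as stored in the file.
#' @export
load_preset <- function(name = c("fig4", "fig5", "fig7", "std_fit")) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "famdyn")
  if (!nzchar(path)) stop("preset file not found for: ", name)
  yaml::read_yaml(path)
}

.waveform_from_list <- function(x, onset = 0) {
  drive_waveform(x$amp_slow, x$amp_fast, x$tau_slow, x$tau_fast,
                 offset = x$offset, onset = onset)
}

#' Mean-field parameters from the fitted preset
#'
#' Builds a [meanfield_params()] object from the `"fig5"` preset. The
#' feedforward drive projection I_F uses the same waveform as the overlap
#' drive I_M (the feedforward pre-dependence, like the recurrent one, loads on
#' the high-rank stimuli); its separate scale is absorbed in the fitted
#' \eqn{\bar f_F}.
#'
#' @param successive logical; replace the single-presentation waveforms by the
#'   successive-presentation schedule (`n_stimuli` onsets spaced by the preset
#'   presentation duration, superseded drives decaying exponentially).
#' @param n_stimuli number of successive presentations when
#'   `successive = TRUE`.
#' @param dt Euler step in ms.
#' @return a [meanfield_params()] object.
#' @export
preset_meanfield <- function(successive = FALSE, n_stimuli = 2, dt = 0.5) {
  p <- load_preset("fig5")
  w_mean <- .waveform_from_list(p$drive_mean)
  w_m <- .waveform_from_list(p$drive_m)
  if (successive) {
    s <- p$successive
    w_mean <- successive_schedule(w_mean, n_stimuli, s$present_ms,
                                  decay = s$decay, tau_decay = s$tau_decay)
    w_m <- successive_schedule(w_m, n_stimuli, s$present_ms,
                               decay = s$decay, tau_decay = s$tau_decay)
  }
  meanfield_params(recurrent_scale = p$recurrent_scale,
                   adapt_strength = p$adapt_strength,
                   tau_rate = p$tau_rate, tau_adapt = p$tau_adapt,
                   fgbar_R = p$fgbar_R, fbar_R = p$fbar_R,
                   fbar_F = p$fbar_F, fgbar_F = p$fgbar_F,
                   drive_mean = w_mean, drive_m = w_m, drive_f = w_m,
                   dt = dt)
}

#' Competition-model pieces from the preset
#'
#' @param dt Euler step in ms.
#' @return list with `params` (a [meanfield_params()] whose `drive_m` holds
#'   the shared waveform), `mutual_inhibition`, `transfer` and `onsets`.
#' @export
preset_competition <- function(dt = 0.5) {
  p <- load_preset("fig7")
  params <- meanfield_params(adapt_strength = p$adapt_strength,
                             tau_rate = p$tau_rate, tau_adapt = p$tau_adapt,
                             fgbar_R = p$fgbar_R,
                             drive_m = .waveform_from_list(p$drive),
                             dt = dt)
  list(params = params, mutual_inhibition = p$mutual_inhibition,
       transfer = rectified_transfer(p$transfer_threshold),
       onsets = c(0, p$onset_gap))
}

#' Example-network configuration from the preset
#'
#' Assembles everything needed to run the example network before and after
#' learning: parameters, gamma-distributed selectivities, pre/post recurrent
#' weights (uniform, then plus the Hebbian update), and pre/post drives (the
#' learned drive scales the time-varying component down by the fitted
#' feedforward gain). The constant input is solved from the closed-form fixed
#' point so the baseline rate matches the preset.
#'
#' @param seed RNG seed for the selectivity draw.
#' @param n_units override the preset network size (e.g. for quick runs).
#' @param dt Euler step in ms.
#' @return list with `params`, `selectivity`, `weights_pre`, `weights_post`,
#'   `drive_pre`, `drive_post`, `baseline_input`.
#' @export
preset_network <- function(seed = 1, n_units = NULL, dt = 0.5) {
  p <- load_preset("fig4")
  n <- if (is.null(n_units)) p$n_units else n_units
  params <- network_params(n_units = n, tau_rate = p$tau_rate,
                           tau_adapt = p$tau_adapt,
                           adapt_strength = p$adapt_strength,
                           recurrent_scale = p$recurrent_scale, dt = dt)
  xi <- sample_selectivity(n, shape = p$xi_shape, seed = seed)
  w_pre <- matrix(p$recurrent_scale / n, n, n)
  w_post <- w_pre + hebbian_delta(xi, p$hebbian_strength)
  # baseline input giving the preset baseline rate at the fixed point
  I_const <- p$baseline_rate *
    (1 - p$recurrent_scale + p$adapt_strength)
  wave <- .waveform_from_list(p$drive)
  list(params = params, selectivity = xi,
       weights_pre = w_pre, weights_post = w_post,
       drive_pre = stimulus_drive(I_const, xi, wave, feedforward_gain = 1),
       drive_post = stimulus_drive(I_const, xi, wave,
                                   feedforward_gain = p$feedforward_gain_learned),
       baseline_input = I_const)
}
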