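#' Network parameter set
#'
#' Collects the parameters of the rate network
#' \deqn{\tau_r \dot r_i = -r_i + \Phi\left(\sum_j W^R_{ij} r_j - k a_i +
#'   I_i(t)\right), \qquad \tau_a \dot a_i = -a_i + r_i,}
#' where the adaptation variable \eqn{a_i} is a low-pass filtered copy of the
#' firing rate with strength `adapt_strength` (k) and time constant
#' `tau_adapt`. Before learning the recurrent weights are uniform,
#' \eqn{W^R_{ij} = w_R / N}.
#'
#' @param n_units number of units N.
#' @param tau_rate rate time constant in ms.
#' @param tau_adapt adaptation time constant in ms.
#' @param adapt_strength adaptation strength k (dimensionless).
#' @param recurrent_scale uniform pre-learning recurrent strength w_R.
#' @param dt integration step in ms; must satisfy `dt <= tau_rate`.
#' @param adaptation_enabled logical; when `FALSE` the adaptation variable is
#'   held at zero.
#' @param clip_rates logical; clip rates at zero after each step (off by
#'   default — the linear theory permits negative rates).
#' @return a list of class `"network_params"`.
#' @export
network_params <- function(n_units, tau_rate = 5, tau_adapt = 200,
                           adapt_strength = 1.8, recurrent_scale = 0,
                           dt = 0.5, adaptation_enabled = TRUE,
                           clip_rates = FALSE) {
  stopifnot(n_units >= 1, tau_rate > 0, tau_adapt > 0, dt > 0,
            dt <= tau_rate)
  structure(list(n_units = as.integer(n_units), tau_rate = tau_rate,
                 tau_adapt = tau_adapt, adapt_strength = adapt_strength,
                 recurrent_scale = recurrent_scale, dt = dt,
                 adaptation_enabled = adaptation_enabled,
                 clip_rates = clip_rates),
            class = "network_params")
}

#' Per-unit stimulus drive
#'
#' Each unit receives \eqn{I_i(t) = baseline + \gamma \xi_i w(t)} where
#' \eqn{\xi_i} is the unit's stimulus selectivity, \eqn{w(t)} the shared
#' time-varying waveform (or schedule) and \eqn{\gamma} the feedforward gain —
#' the quantity scaled down by feedforward depression after learning.
#'
#' @param baseline constant input component.
#' @param selectivity per-unit amplitudes \eqn{\xi_i}.
#' @param waveform a `"drive_waveform"`, `"drive_schedule"`, constant, or
#'   function of time.
#' @param feedforward_gain scaling \eqn{\gamma} of the time-varying component.
#' @export
stimulus_drive <- function(baseline, selectivity, waveform,
                           feedforward_gain = 1) {
  structure(list(baseline = baseline, selectivity = selectivity,
                 waveform = waveform, feedforward_gain = feedforward_gain),
            class = "stimulus_drive")
}

# Evaluate the per-unit drive at one time point -> length-N vector.
.unit_drive <- function(drive, t, n_units) {
  if (is.function(drive)) {
    v <- drive(t)
    if (length(v) == 1L) v <- rep(v, n_units)
    return(v)
  }
  if (inherits(drive, "stimulus_drive")) {
    stopifnot(length(drive$selectivity) == n_units)
    return(drive$baseline +
             drive$feedforward_gain * drive$selectivity *
             drive_value(drive$waveform, t))
  }
  if (is.numeric(drive)) {
    if (length(drive) == 1L) return(rep(drive, n_units))
    stopifnot(length(drive) == n_units)
    return(drive)
  }
  stop("unsupported drive specification")
}

#' Fixed point of the linear network under constant drive
#'
#' Solves \eqn{r = W r - k r + I} (adaptation at its steady state `a = r`)
#' for the linear transfer function.
#'
#' @param params a `"network_params"` object.
#' @param weights recurrent weight matrix.
#' @param input constant per-unit input (scalar or length-N).
#' @return the steady-state rate vector.
#' @export
network_fixed_point <- function(params, weights, input) {
  n <- params$n_units
  k <- if (params$adaptation_enabled) params$adapt_strength else 0
  input <- if (length(input) == 1L) rep(input, n) else input
  solve(diag(1 + k, n) - weights, input)
}

#' Simulate the rate network
#'
#' Forward-Euler integration of the rate equations with optional firing-rate
#' adaptation. Aborts with a diagnostic naming the first bad time step if the
#' state becomes non-finite (instability).
#'
#' @param params a [network_params()] object.
#' @param weights N x N recurrent weight matrix (post x pre). If `NULL`, the
#'   uniform pre-learning connectivity `recurrent_scale / N` is used.
#' @param drive a [stimulus_drive()], a function of time returning per-unit
#'   input, a constant, or a length-N vector.
#' @param transfer a `"transfer_fun"`; default linear.
#' @param duration simulated time in ms.
#' @param initial_state optional list with elements `rates` and `adaptation`;
#'   by default, for the linear transfer, the network starts at the fixed
#'   point of the constant part of the drive (zero otherwise).
#' @return An object of class `"network_trajectory"`: list with `times` (ms),
#'   `rates` (units x time) and `adaptation` (units x time).
#' @export
simulate_network <- function(params, weights = NULL, drive,
                             transfer = linear_transfer(), duration,
                             initial_state = NULL) {
  stopifnot(inherits(params, "network_params"), duration >= params$dt)
  n <- params$n_units
  if (is.null(weights)) weights <- matrix(params$recurrent_scale / n, n, n)
  stopifnot(nrow(weights) == n, ncol(weights) == n)
  dt <- params$dt
  k <- params$adapt_strength
  times <- seq(0, duration, by = dt)
  n_t <- length(times)

  if (is.null(initial_state)) {
    base <- if (inherits(drive, "stimulus_drive")) rep(drive$baseline, n)
            else .unit_drive(drive, times[1L], n) * 0
    if (transfer$kind == "linear") {
      r <- network_fixed_point(params, weights, base)
    } else r <- numeric(n)
    a <- if (params$adaptation_enabled) r else numeric(n)
  } else {
    r <- initial_state$rates
    a <- if (is.null(initial_state$adaptation)) numeric(n)
         else initial_state$adaptation
  }

  rates <- matrix(NA_real_, n, n_t)
  adapt <- matrix(NA_real_, n, n_t)
  rates[, 1L] <- r
  adapt[, 1L] <- a
  for (s in seq_len(n_t - 1L)) {
    input <- .unit_drive(drive, times[s], n)
    tot <- drop(weights %*% r) - k * a + input
    r_new <- r + dt / params$tau_rate * (-r + phi(transfer, tot))
    if (params$clip_rates) r_new <- pmax(r_new, 0)
    a_new <- if (params$adaptation_enabled)
      a + dt / params$tau_adapt * (-a + r) else a
    if (any(!is.finite(r_new)))
      stop(sprintf("network state non-finite at step %d (t = %g ms): unstable",
                   s + 1L, times[s + 1L]))
    r <- r_new; a <- a_new
    rates[, s + 1L] <- r
    adapt[, s + 1L] <- a
  }
  structure(list(times = times, rates = rates, adaptation = adapt),
            class = "network_trajectory")
}

#' Simulate the network with short-term synaptic depression
#'
#' Rates and per-source synaptic resources are co-integrated:
#' \deqn{\tau_r \dot r_i = -r_i + \Phi\left(\sum_j W_{ij} x_j r_j + I_i\right),
#'  \qquad \dot x_j = (1 - x_j)/\tau_x - \gamma x_j r_j,}
#' where \eqn{x_j \in (0, 1]} is the fraction of presynaptic resources and
#' \eqn{\gamma} the depletion strength. Resources start at the steady state
#' for the baseline rate. Adaptation is off by default in this variant (the
#' depression itself is the negative feedback under study).
#'
#' @inheritParams simulate_network
#' @param tau_recover resource recovery time constant \eqn{\tau_x} in ms.
#' @param depletion_strength depletion rate \eqn{\gamma} per unit rate;
#'   must be nonnegative.
#' @return A `"network_trajectory"` with an extra element `resources`
#'   (units x time).
#' @export
simulate_std_network <- function(params, weights = NULL, drive,
                                 transfer = linear_transfer(), duration,
                                 tau_recover = 200, depletion_strength = 0.125,
                                 initial_state = NULL) {
  stopifnot(inherits(params, "network_params"), duration >= params$dt,
            tau_recover > 0, depletion_strength >= 0)
  n <- params$n_units
  if (is.null(weights)) weights <- matrix(params$recurrent_scale / n, n, n)
  dt <- params$dt
  k <- if (params$adaptation_enabled) params$adapt_strength else 0
  times <- seq(0, duration, by = dt)
  n_t <- length(times)

  if (is.null(initial_state)) {
    r <- numeric(n)
    a <- numeric(n)
  } else {
    r <- initial_state$rates
    a <- if (is.null(initial_state$adaptation)) numeric(n)
         else initial_state$adaptation
  }
  # resource steady state at the baseline rate
  x <- 1 / (1 + depletion_strength * tau_recover * pmax(r, 0))

  rates <- matrix(NA_real_, n, n_t); adapt <- matrix(NA_real_, n, n_t)
  res <- matrix(NA_real_, n, n_t)
  rates[, 1L] <- r; adapt[, 1L] <- a; res[, 1L] <- x
  for (s in seq_len(n_t - 1L)) {
    input <- .unit_drive(drive, times[s], n)
    tot <- drop(weights %*% (x * r)) - k * a + input
    r_new <- r + dt / params$tau_rate * (-r + phi(transfer, tot))
    x_new <- .std_resource_step(x, r, dt, tau_recover, depletion_strength)
    a_new <- if (params$adaptation_enabled)
      a + dt / params$tau_adapt * (-a + r) else a
    if (any(!is.finite(r_new)) || any(!is.finite(x_new)))
      stop(sprintf("network state non-finite at step %d (t = %g ms): unstable",
                   s + 1L, times[s + 1L]))
    r <- r_new; x <- x_new; a <- a_new
    rates[, s + 1L] <- r; res[, s + 1L] <- x; adapt[, s + 1L] <- a
  }
  structure(list(times = times, rates = rates, adaptation = adapt,
                 resources = res),
            class = "network_trajectory")
}

#' @export
print.network_trajectory <- function(x, ...) {
  cat(sprintf("Network trajectory: %d units, %d steps (%g..%g ms)\n",
              nrow(x$rates), length(x$times), min(x$times), max(x$times)))
  if (!is.null(x$resources)) cat("  includes short-term-depression resources\n")
  invisible(x)
}

#' Export a trajectory as a long-format data frame
#'
#' @param x a `"network_trajectory"`.
#' @param row.names,optional unused, for S3 compatibility.
#' @param ... unused.
#' @return data.frame with columns time_ms, unit, rate, adaptation (and
#'   resources when present).
#' @export
as.data.frame.network_trajectory <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  n <- nrow(x$rates); n_t <- length(x$times)
  d <- data.frame(time_ms = rep(x$times, each = n),
                  unit = rep(seq_len(n), n_t),
                  rate = as.vector(x$rates),
                  adaptation = as.vector(x$adaptation))
  if (!is.null(x$resources)) d$resources <- as.vector(x$resources)
  d
}
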