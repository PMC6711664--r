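#' Mean-field parameter set
#'
#' Parameters of the reduced description of the learned network. Before
#' learning the dynamics is two-dimensional in the population averages
#' \eqn{(\bar r, \bar a)}; after learning the overlap with the stored pattern
#' and its adaptation, \eqn{(m, n)}, are appended:
#' \deqn{\tau_R \dot{\bar r} = -\bar r + w_R \bar r + \bar f_R m - k \bar a +
#'   \bar I(t) + \bar f_F I_F(t)}
#' \deqn{\tau_A \dot{\bar a} = -\bar a + \bar r}
#' \deqn{\tau_R \dot m = -m + \overline{fg}_R m - k n + I_M(t) +
#'   \overline{fg}_F I_F(t)}
#' \deqn{\tau_A \dot n = -n + m}
#'
#' @param recurrent_scale pre-learning uniform recurrent strength w_R.
#' @param adapt_strength adaptation strength k.
#' @param tau_rate,tau_adapt time constants in ms.
#' @param fgbar_R,fbar_R,fbar_F,fgbar_F plasticity-induced mean-field
#'   coefficients (see [meanfield_coefficients()]).
#' @param drive_mean,drive_m,drive_f drives \eqn{\bar I, I_M, I_F}: each a
#'   [drive_waveform()], [successive_schedule()], constant, or function of
#'   time.
#' @param dt Euler step in ms.
#' @return list of class `"meanfield_params"`.
#' @export
meanfield_params <- function(recurrent_scale = 0, adapt_strength = 1.8,
                             tau_rate = 5, tau_adapt = 200,
                             fgbar_R = 0, fbar_R = 0, fbar_F = 0, fgbar_F = 0,
                             drive_mean = 0, drive_m = 0, drive_f = 0,
                             dt = 0.5) {
  stopifnot(tau_rate > 0, tau_adapt > 0, dt > 0, dt <= tau_rate)
  structure(list(recurrent_scale = recurrent_scale,
                 adapt_strength = adapt_strength,
                 tau_rate = tau_rate, tau_adapt = tau_adapt,
                 fgbar_R = fgbar_R, fbar_R = fbar_R,
                 fbar_F = fbar_F, fgbar_F = fgbar_F,
                 drive_mean = drive_mean, drive_m = drive_m,
                 drive_f = drive_f, dt = dt),
            class = "meanfield_params")
}

.mf_traj <- function(times, rbar, abar, m, n, extra = NULL) {
  structure(c(list(times = times, rbar = rbar, abar = abar, m = m, n = n),
              extra),
            class = "meanfield_trajectory")
}

#' Simulate the reduced mean-field dynamics
#'
#' Euler integration of the four-variable learned system; with
#' `learned = FALSE` the plasticity coefficients and the (m, n) block are
#' zeroed, recovering the two-variable pre-learning dynamics.
#'
#' @param params a [meanfield_params()] object.
#' @param duration simulated time in ms.
#' @param learned logical; include the learned (m, n) block.
#' @param init numeric length-4 initial state `(rbar, abar, m, n)`.
#' @return object of class `"meanfield_trajectory"` with fields `times`,
#'   `rbar`, `abar`, `m`, `n`.
#' @export
simulate_meanfield <- function(params, duration, learned = TRUE,
                               init = c(0, 0, 0, 0)) {
  stopifnot(inherits(params, "meanfield_params"), duration >= params$dt,
            length(init) == 4L)
  p <- params
  dt <- p$dt
  times <- seq(0, duration, by = dt)
  n_t <- length(times)
  Imean <- drive_value(p$drive_mean, times)
  IM <- drive_value(p$drive_m, times)
  IF_ <- drive_value(p$drive_f, times)
  fbR <- if (learned) p$fbar_R else 0
  fbF <- if (learned) p$fbar_F else 0
  fgR <- if (learned) p$fgbar_R else 0
  fgF <- if (learned) p$fgbar_F else 0

  rbar <- numeric(n_t); abar <- numeric(n_t)
  m <- numeric(n_t); n <- numeric(n_t)
  st <- init
  if (!learned) st[3:4] <- 0
  rbar[1L] <- st[1L]; abar[1L] <- st[2L]; m[1L] <- st[3L]; n[1L] <- st[4L]
  for (s in seq_len(n_t - 1L)) {
    dr <- (-st[1L] + p$recurrent_scale * st[1L] + fbR * st[3L] -
             p$adapt_strength * st[2L] + Imean[s] + fbF * IF_[s]) / p$tau_rate
    da <- (-st[2L] + st[1L]) / p$tau_adapt
    if (learned) {
      dm <- (-st[3L] + fgR * st[3L] - p$adapt_strength * st[4L] +
               IM[s] + fgF * IF_[s]) / p$tau_rate
      dn <- (-st[4L] + st[3L]) / p$tau_adapt
    } else dm <- dn <- 0
    st <- st + dt * c(dr, da, dm, dn)
    if (any(!is.finite(st)))
      stop(sprintf("mean-field state non-finite at step %d (t = %g ms): unstable",
                   s + 1L, times[s + 1L]))
    rbar[s + 1L] <- st[1L]; abar[s + 1L] <- st[2L]
    m[s + 1L] <- st[3L]; n[s + 1L] <- st[4L]
  }
  .mf_traj(times, rbar, abar, m, n)
}

#' Simulate the global-inhibition variant
#'
#' All units receive the same slow inhibition \eqn{a^I}, a low-pass filtered
#' copy of the population mean rate with strength \eqn{k^I}. The overlap m
#' then obeys a first-order equation with no private negative feedback, so it
#' cannot produce damped oscillations:
#' \deqn{\tau_R \dot{\bar r} = -\bar r + w_R \bar r + \bar f_R m - k^I a^I +
#'   \bar I + \bar f_F I_F, \quad
#'   \tau_A \dot a^I = -a^I + \bar r, \quad
#'   \tau_R \dot m = -m + \overline{fg}_R m + I_M + \overline{fg}_F I_F.}
#'
#' @param params a [meanfield_params()] object; `adapt_strength` is reused as
#'   the inhibition strength \eqn{k^I}.
#' @param duration simulated time in ms.
#' @param init numeric length-3 initial state `(rbar, aI, m)`.
#' @return a `"meanfield_trajectory"`; the `abar` field holds \eqn{a^I} and
#'   `n` is identically zero.
#' @export
simulate_global_inhibition <- function(params, duration, init = c(0, 0, 0)) {
  stopifnot(inherits(params, "meanfield_params"), duration >= params$dt,
            length(init) == 3L)
  p <- params
  dt <- p$dt
  times <- seq(0, duration, by = dt)
  n_t <- length(times)
  Imean <- drive_value(p$drive_mean, times)
  IM <- drive_value(p$drive_m, times)
  IF_ <- drive_value(p$drive_f, times)

  rbar <- numeric(n_t); aI <- numeric(n_t); m <- numeric(n_t)
  st <- init
  rbar[1L] <- st[1L]; aI[1L] <- st[2L]; m[1L] <- st[3L]
  for (s in seq_len(n_t - 1L)) {
    dr <- (-st[1L] + p$recurrent_scale * st[1L] + p$fbar_R * st[3L] -
             p$adapt_strength * st[2L] + Imean[s] + p$fbar_F * IF_[s]) / p$tau_rate
    da <- (-st[2L] + st[1L]) / p$tau_adapt
    dm <- (-st[3L] + p$fgbar_R * st[3L] + IM[s] + p$fgbar_F * IF_[s]) / p$tau_rate
    st <- st + dt * c(dr, da, dm)
    if (any(!is.finite(st)))
      stop(sprintf("mean-field state non-finite at step %d (t = %g ms): unstable",
                   s + 1L, times[s + 1L]))
    rbar[s + 1L] <- st[1L]; aI[s + 1L] <- st[2L]; m[s + 1L] <- st[3L]
  }
  .mf_traj(times, rbar, aI, m, numeric(n_t))
}

#' Simulate the reduced short-term-depression model
#'
#' Two-variable description of the high-rate population when synaptic
#' depression, rather than adaptation, supplies the negative feedback:
#' \deqn{\tau_r \dot r = -r + \overline{fg}\, x\, r + I_M(t), \qquad
#'   \dot x = (1 - x)/\tau_x - \gamma x r.}
#'
#' @param fg_strength learned recurrent strength \eqn{f^R_m g^R_m}.
#' @param depletion_strength depression strength \eqn{\gamma} (nonnegative).
#' @param tau_rate rate time constant in ms.
#' @param tau_recover resource recovery time constant \eqn{\tau_x} in ms.
#' @param drive the input \eqn{I_M(t)} (waveform, schedule, constant, or
#'   function).
#' @param duration simulated time in ms.
#' @param dt Euler step in ms.
#' @param baseline_rate rate used to initialize the resources at their steady
#'   state.
#' @return list of class `"std_trajectory"` with `times`, `rate`, `resources`.
#' @export
simulate_std_reduced <- function(fg_strength, depletion_strength,
                                 tau_rate = 5, tau_recover = 200,
                                 drive, duration, dt = 0.5,
                                 baseline_rate = 0) {
  stopifnot(fg_strength >= 0, depletion_strength >= 0,
            tau_rate > 0, tau_recover > 0, dt > 0, duration >= dt)
  times <- seq(0, duration, by = dt)
  n_t <- length(times)
  I <- drive_value(drive, times)
  r <- baseline_rate
  x <- 1 / (1 + depletion_strength * tau_recover * max(baseline_rate, 0))
  rate <- numeric(n_t); res <- numeric(n_t)
  rate[1L] <- r; res[1L] <- x
  for (s in seq_len(n_t - 1L)) {
    r_new <- r + dt / tau_rate * (-r + fg_strength * x * r + I[s])
    x_new <- .std_resource_step(x, r, dt, tau_recover, depletion_strength)
    if (!is.finite(r_new) || !is.finite(x_new))
      stop(sprintf("STD state non-finite at step %d (t = %g ms): unstable",
                   s + 1L, times[s + 1L]))
    r <- r_new; x <- x_new
    rate[s + 1L] <- r; res[s + 1L] <- x
  }
  structure(list(times = times, rate = rate, resources = res),
            class = "std_trajectory")
}

# One integration step of the resource equation
#   dx/dt = (1 - x)/tau_x - gamma * x * r
# by exponential Euler (exact with the rate frozen over the step). Unlike the
# explicit update this is unconditionally stable and keeps x in (0, 1] for
# nonnegative rates, including on the coarse 5 ms data grid where
# gamma * r * dt can exceed 1.
.std_resource_step <- function(x, r, dt, tau_recover, depletion_strength) {
  lam <- 1 / tau_recover + depletion_strength * r
  xinf <- (1 / tau_recover) / lam
  out <- xinf + (x - xinf) * exp(-lam * dt)
  ifelse(lam == 0, x + dt / tau_recover, out)
}

#' Simulate two competing familiar-stimulus populations
#'
#' Two mutually inhibitory populations, each following the overlap dynamics of
#' a single familiar stimulus, with a piecewise-linear transfer:
#' \deqn{\tau_R \dot m_i = -m_i + \Phi(\overline{fg}_R m_i - k n_i -
#'   w_c m_j + I_{m,i}(t)), \qquad \tau_A \dot n_i = -n_i + m_i.}
#' Population 2 is silent before its stimulus onset: its state is frozen at
#' zero and released at onset.
#'
#' @param params a [meanfield_params()]; `drive_m` supplies the shared input
#'   waveform (evaluated on each population's own clock via its onset).
#' @param mutual_inhibition competition strength \eqn{w_c}.
#' @param transfer the competition nonlinearity; default
#'   `rectified_transfer(-3)`.
#' @param onsets length-2 stimulus onsets in ms.
#' @param duration simulated time in ms.
#' @return list of class `"competition_trajectory"` with `times`, `m`
#'   (2 x time), `n` (2 x time), `onsets`.
#' @export
simulate_competition <- function(params, mutual_inhibition = 0.1,
                                 transfer = rectified_transfer(-3),
                                 onsets = c(0, 500), duration) {
  stopifnot(inherits(params, "meanfield_params"), length(onsets) == 2L,
            duration >= params$dt)
  p <- params
  dt <- p$dt
  times <- seq(0, duration, by = dt)
  n_t <- length(times)
  # per-population drive: shared waveform on each population's own clock
  Idrv <- sapply(onsets, function(o) {
    w <- p$drive_m
    if (inherits(w, "drive_waveform")) { w$onset <- o; drive_value(w, times) }
    else drive_value(w, times - o)
  })
  m <- matrix(0, 2L, n_t); n <- matrix(0, 2L, n_t)
  mc <- c(0, 0); nc <- c(0, 0)
  for (s in seq_len(n_t - 1L)) {
    live <- times[s] >= onsets          # frozen (silent) before own onset
    inp <- p$fgbar_R * mc - p$adapt_strength * nc -
      mutual_inhibition * rev(mc) + Idrv[s, ]
    dm <- (-mc + phi(transfer, inp)) / p$tau_rate
    dn <- (-nc + mc) / p$tau_adapt
    mc <- mc + dt * dm * live
    nc <- nc + dt * dn * live
    if (any(!is.finite(mc)))
      stop(sprintf("competition state non-finite at step %d (t = %g ms): unstable",
                   s + 1L, times[s + 1L]))
    m[, s + 1L] <- mc; n[, s + 1L] <- nc
  }
  structure(list(times = times, m = m, n = n, onsets = onsets),
            class = "competition_trajectory")
}

#' @export
print.meanfield_trajectory <- function(x, ...) {
  cat(sprintf("Mean-field trajectory: %d steps (%g..%g ms)\n",
              length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  final state: rbar = %.4g, abar = %.4g, m = %.4g, n = %.4g\n",
              x$rbar[length(x$rbar)], x$abar[length(x$abar)],
              x$m[length(x$m)], x$n[length(x$n)]))
  invisible(x)
}

#' @export
as.data.frame.meanfield_trajectory <- function(x, row.names = NULL,
                                               optional = FALSE, ...) {
  data.frame(time_ms = x$times, rbar = x$rbar, abar = x$abar,
             m = x$m, n = x$n)
}

#' @export
plot.meanfield_trajectory <- function(x, ...) {
  graphics::matplot(x$times, cbind(x$rbar, x$m), type = "l", lty = 1,
                    col = c("black", "firebrick"),
                    xlab = "time (ms)", ylab = "activity", ...)
  graphics::legend("topright", c("mean rate", "overlap m"),
                   col = c("black", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' Locate local maxima of a sampled trace
#'
#' Utility used to count rebounds and to measure damped-oscillation periods:
#' indices s with `x[s-1] < x[s] >= x[s+1]` whose prominence above the
#' surrounding minima exceeds `min_prominence`.
#'
#' @param x numeric trace.
#' @param min_prominence minimum rise above the neighbouring minima for a peak
#'   to count.
#' @return integer vector of peak indices.
#' @export
local_maxima <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  idx <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  if (min_prominence > 0 && length(idx)) {
    keep <- vapply(idx, function(i) {
      left <- min(x[1:i]); right <- min(x[i:n])
      (x[i] - max(left, right)) >= min_prominence
    }, logical(1L))
    idx <- idx[keep]
  }
  idx
}

#' Dominant period of a damped oscillatory trace
#'
#' Estimates the oscillation period as the interval between the first two
#' local maxima, refined by parabolic interpolation around each peak.
#' Returns `NA` if fewer than two peaks are found.
#'
#' @param x numeric trace.
#' @param dt sampling step in ms.
#' @param min_prominence passed to [local_maxima()].
#' @return period in ms, or `NA`.
#' @export
dominant_period <- function(x, dt, min_prominence = 0) {
  pk <- local_maxima(x, min_prominence)
  if (length(pk) < 2L) return(NA_real_)
  refine <- function(i) {
    if (i <= 1L || i >= length(x)) return(i)
    y0 <- x[i - 1L]; y1 <- x[i]; y2 <- x[i + 1L]
    den <- y0 - 2 * y1 + y2
    if (den == 0) return(i)
    i + 0.5 * (y0 - y2) / den
  }
  (refine(pk[2L]) - refine(pk[1L])) * dt
}
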