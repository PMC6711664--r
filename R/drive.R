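#' Double-exponential stimulus drive waveform
#'
#' External inputs are modelled as a difference of two exponentials,
#' \deqn{I(t) = a e^{-t/\tau_s} - b e^{-t/\tau_f} + c,}
#' evaluated on the waveform clock \eqn{t' = t - onset} and 0 before onset.
#' With the convention \eqn{c = b - a} the waveform starts at 0 and decays to
#' \eqn{b - a}; with \eqn{a = b} and \eqn{c = 0} it is a transient pulse.
#'
#' @param amp_slow amplitude of the slow exponential (rate units).
#' @param amp_fast amplitude of the fast exponential (rate units).
#' @param tau_slow,tau_fast time constants in ms; must be positive.
#' @param offset additive constant after onset; defaults to
#'   `amp_fast - amp_slow` so the waveform is 0 at onset.
#' @param onset stimulus onset time in ms.
#' @return An object of class `"drive_waveform"`; it can be evaluated with
#'   [drive_value()].
#' @examples
#' w <- drive_waveform(1, 1, 150, 50)
#' drive_value(w, c(0, 82.4, 500))
#' @export
drive_waveform <- function(amp_slow, amp_fast, tau_slow, tau_fast,
                           offset = amp_fast - amp_slow, onset = 0) {
  if (!is.finite(tau_slow) || !is.finite(tau_fast) ||
      tau_slow <= 0 || tau_fast <= 0)
    stop("drive time constants must be positive and finite")
  structure(list(amp_slow = amp_slow, amp_fast = amp_fast,
                 tau_slow = tau_slow, tau_fast = tau_fast,
                 offset = offset, onset = onset),
            class = "drive_waveform")
}

#' Evaluate a drive waveform or schedule
#'
#' @param drive a `"drive_waveform"`, a `"drive_schedule"`, a constant, or a
#'   function of time (ms) returning the drive value.
#' @param t numeric vector of times in ms.
#' @return numeric vector of drive values.
#' @export
drive_value <- function(drive, t) {
  if (is.numeric(drive) && length(drive) == 1L) return(rep(drive, length(t)))
  if (is.function(drive)) return(vapply(t, drive, numeric(1L)))
  if (inherits(drive, "drive_schedule")) return(.schedule_value(drive, t))
  stopifnot(inherits(drive, "drive_waveform"))
  tr <- t - drive$onset
  v <- drive$amp_slow * exp(-tr / drive$tau_slow) -
       drive$amp_fast * exp(-tr / drive$tau_fast) + drive$offset
  v[tr < 0] <- 0
  v
}

#' Successive-presentation drive schedule
#'
#' Builds the piecewise drive used for successive stimulus presentations: the
#' waveform of each stimulus restarts at its onset, and once the next stimulus
#' comes on the previous drive decays by the chosen law — linearly to zero over
#' `decay_ms`, or exponentially with time constant `tau_decay` — from the value
#' it had at the switch.
#'
#' @param waveform the per-stimulus `"drive_waveform"` (onsets are supplied
#'   separately; its own `onset` field is ignored).
#' @param n_stimuli number of successive presentations.
#' @param present_ms presentation duration of each stimulus (onset spacing).
#' @param decay `"exponential"` or `"linear"` decay of the superseded drive.
#' @param tau_decay exponential decay time constant in ms.
#' @param decay_ms duration of the linear decay in ms.
#' @param onset onset of the first stimulus in ms.
#' @return An object of class `"drive_schedule"`, evaluable via [drive_value()];
#'   `component_value()` evaluates a single stimulus' contribution.
#' @export
successive_schedule <- function(waveform, n_stimuli, present_ms,
                                decay = c("exponential", "linear"),
                                tau_decay = 50, decay_ms = present_ms,
                                onset = 0) {
  decay <- match.arg(decay)
  stopifnot(inherits(waveform, "drive_waveform"),
            n_stimuli >= 1L, present_ms > 0,
            tau_decay > 0, decay_ms > 0)
  structure(list(waveform = waveform, n_stimuli = as.integer(n_stimuli),
                 present_ms = present_ms, decay = decay,
                 tau_decay = tau_decay, decay_ms = decay_ms, onset = onset),
            class = "drive_schedule")
}

#' @rdname successive_schedule
#' @param schedule a `"drive_schedule"`.
#' @param i stimulus index (1-based).
#' @param t numeric vector of times in ms.
#' @export
component_value <- function(schedule, i, t) {
  stopifnot(inherits(schedule, "drive_schedule"),
            i >= 1L, i <= schedule$n_stimuli)
  w <- schedule$waveform
  w$onset <- 0
  o_i <- schedule$onset + (i - 1) * schedule$present_ms
  switch_t <- o_i + schedule$present_ms            # next stimulus onset
  active <- i == schedule$n_stimuli                # last stimulus never decays
  v <- drive_value(w, t - o_i)
  if (!active) {
    v_switch <- drive_value(w, schedule$present_ms)
    after <- t >= switch_t
    if (schedule$decay == "exponential") {
      v[after] <- v_switch * exp(-(t[after] - switch_t) / schedule$tau_decay)
    } else {
      v[after] <- v_switch * pmax(0, 1 - (t[after] - switch_t) / schedule$decay_ms)
    }
  }
  v
}

.schedule_value <- function(schedule, t) {
  v <- numeric(length(t))
  for (i in seq_len(schedule$n_stimuli))
    v <- v + component_value(schedule, i, t)
  v
}

#' @export
print.drive_waveform <- function(x, ...) {
  cat(sprintf(
    "Drive waveform: %g*exp(-t/%g) - %g*exp(-t/%g) %+g, onset %g ms\n",
    x$amp_slow, x$tau_slow, x$amp_fast, x$tau_fast, x$offset, x$onset))
  invisible(x)
}

#' @export
print.drive_schedule <- function(x, ...) {
  cat(sprintf("Successive drive schedule: %d stimuli every %g ms, %s decay\n",
              x$n_stimuli, x$present_ms, x$decay))
  invisible(x)
}
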