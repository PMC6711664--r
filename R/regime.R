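#' Eigenvalues of the two-variable linear block
#'
#' Both the pre-learning \eqn{(\bar r, \bar a)} dynamics and the learned
#' \eqn{(m, n)} block are governed by the 2 x 2 matrix
#' \deqn{A = \begin{pmatrix} (w - 1)/\tau_R & -k/\tau_R \\
#'   1/\tau_A & -1/\tau_A \end{pmatrix},}
#' with `feedback` w equal to \eqn{w_R} (before learning) or
#' \eqn{\overline{fg}_R} (after learning). Eigenvalues are
#' \eqn{(\mathrm{tr} \pm \sqrt{\mathrm{disc}})/2} with
#' \eqn{\mathrm{disc} = \{(w-1)/\tau_R + 1/\tau_A\}^2 - 4k/(\tau_R \tau_A)}.
#'
#' @param feedback recurrent feedback strength w.
#' @param k adaptation strength.
#' @param tau_rate,tau_adapt time constants in ms.
#' @return complex pair of eigenvalues (1/ms), slowest-decaying first.
#' @export
eigenvalues_2d <- function(feedback, k, tau_rate, tau_adapt) {
  stopifnot(tau_rate > 0, tau_adapt > 0)
  tr <- (feedback - 1) / tau_rate - 1 / tau_adapt
  disc <- ((feedback - 1) / tau_rate + 1 / tau_adapt)^2 -
    4 * k / (tau_rate * tau_adapt)
  sq <- sqrt(as.complex(disc))
  lam <- c((tr + sq) / 2, (tr - sq) / 2)
  lam[order(-Re(lam))]
}

#' Classify the dynamical regime of the two-variable block
#'
#' Labels the linear block as a stable node (real eigenvalues: monotone /
#' overshoot decay), a stable focus (complex pair: damped oscillation, with
#' period \eqn{2\pi/\mathrm{Im}\,\lambda}), or unstable (some eigenvalue with
#' positive real part, equivalently \eqn{w \ge 1 + \tau_R/\tau_A} or
#' \eqn{w - k - 1 \ge 0} beyond the margin). Boundary cases (zero
#' discriminant, zero real part) are classified by closed-set convention as
#' node / stable; the raw values are reported so callers can apply their own
#' tolerance.
#'
#' @inheritParams eigenvalues_2d
#' @return object of class `"regime_report"`: list with `eigenvalues`,
#'   `discriminant`, `label`, `period` (ms; `NA` unless complex), and the
#'   input parameters.
#' @export
classify_regime <- function(feedback, k, tau_rate, tau_adapt) {
  lam <- eigenvalues_2d(feedback, k, tau_rate, tau_adapt)
  disc <- ((feedback - 1) / tau_rate + 1 / tau_adapt)^2 -
    4 * k / (tau_rate * tau_adapt)
  complex_pair <- disc < 0
  stable <- max(Re(lam)) <= 0
  label <- if (!stable) "unstable"
           else if (complex_pair) "stable_focus" else "stable_node"
  period <- if (complex_pair) 2 * pi / abs(Im(lam[1L])) else NA_real_
  structure(list(eigenvalues = lam, discriminant = disc, label = label,
                 period = period, feedback = feedback, k = k,
                 tau_rate = tau_rate, tau_adapt = tau_adapt),
            class = "regime_report")
}

#' @export
print.regime_report <- function(x, ...) {
  cat("Regime of the 2-variable linear block\n")
  cat(sprintf("  feedback w = %g, k = %g, tau_R = %g ms, tau_A = %g ms\n",
              x$feedback, x$k, x$tau_rate, x$tau_adapt))
  cat(sprintf("  eigenvalues: %.5g %+.5gi, %.5g %+.5gi (1/ms)\n",
              Re(x$eigenvalues[1]), Im(x$eigenvalues[1]),
              Re(x$eigenvalues[2]), Im(x$eigenvalues[2])))
  cat(sprintf("  discriminant: %.5g (1/ms^2)\n", x$discriminant))
  cat("  label:", x$label, "\n")
  if (is.finite(x$period))
    cat(sprintf("  damped-oscillation period: %.4g ms\n", x$period))
  invisible(x)
}

#' Adaptation strength on the node/focus separatrix
#'
#' Solving `discriminant = 0` for k gives the parabola
#' \deqn{k_{sep}(w) = \frac{\tau_R \tau_A}{4}\left(\frac{w - 1}{\tau_R} +
#'   \frac{1}{\tau_A}\right)^2;}
#' above it the block is a focus (damped oscillation), below it a node.
#'
#' @inheritParams eigenvalues_2d
#' @return the separatrix value of k.
#' @export
separatrix_k <- function(feedback, tau_rate, tau_adapt) {
  tau_rate * tau_adapt / 4 *
    ((feedback - 1) / tau_rate + 1 / tau_adapt)^2
}

#' Regime classification over a parameter grid
#'
#' @param feedback_grid,k_grid numeric grids for the feedback strength and
#'   adaptation strength.
#' @inheritParams eigenvalues_2d
#' @return data.frame with columns feedback, k, discriminant, label, period.
#' @export
phase_diagram <- function(feedback_grid, k_grid, tau_rate, tau_adapt) {
  g <- expand.grid(feedback = feedback_grid, k = k_grid)
  rep_list <- Map(function(w, k) classify_regime(w, k, tau_rate, tau_adapt),
                  g$feedback, g$k)
  g$discriminant <- vapply(rep_list, `[[`, numeric(1L), "discriminant")
  g$label <- vapply(rep_list, `[[`, character(1L), "label")
  g$period <- vapply(rep_list, `[[`, numeric(1L), "period")
  g
}

#' Second-peak suppression condition for successive novel stimuli
#'
#' Piecewise-linear approximation of two successive presentations: the rate
#' rises linearly to `r0` over `t0` (constant input `I0`, adaptation frozen),
#' decays linearly to `r1` over `t1`, after which the accumulated adaptation is
#' \deqn{a_1 = r_0 (1 - e^{-t_1/\tau_A}) + (r_1 - r_0)\{1 -
#'   (\tau_A/t_1)(1 - e^{-t_1/\tau_A})\}.}
#' The second rise then reaches \eqn{(I_0 - a_1 k)\, t_0/\tau_{eff} + r_1}
#' with \eqn{I_0 = r_0 \tau_{eff}/t_0} and
#' \eqn{\tau_{eff} = \tau_R/(1 - w_R)}; the experimental constraint is that
#' this second peak lies below the first (`r0`).
#'
#' @param r0,r1 rates at the end of the rising and decaying phases.
#' @param t0,t1 durations (ms) of the rising and decaying phases; positive.
#' @param w_R pre-learning recurrent strength (must be < 1).
#' @param k adaptation strength.
#' @param tau_rate,tau_adapt time constants in ms.
#' @return list with `a1`, `second_peak`, `satisfied`, `tau_eff`, `I0`.
#' @export
second_peak_condition <- function(r0, r1, t0, t1, w_R = 0, k,
                                  tau_rate, tau_adapt) {
  if (t0 <= 0 || t1 <= 0) stop("phase durations t0, t1 must be positive")
  if (w_R >= 1) stop("requires w_R < 1 for a finite effective time constant")
  tau_eff <- tau_rate / (1 - w_R)
  I0 <- r0 * tau_eff / t0
  e1 <- exp(-t1 / tau_adapt)
  a1 <- r0 * (1 - e1) + (r1 - r0) * (1 - (tau_adapt / t1) * (1 - e1))
  second_peak <- (I0 - a1 * k) * t0 / tau_eff + r1
  list(a1 = a1, second_peak = second_peak,
       satisfied = second_peak < r0, tau_eff = tau_eff, I0 = I0)
}
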