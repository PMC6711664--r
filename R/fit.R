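# Shared forward model on the data grid. The rate equation is discretized
# with tau_r equal to the bin width dt, so the update is
#   r(t+dt) = Phi(w_R * rbar(t) + f_R * r_max(t) - k a(t) + I(t) + f_F * I_max(t)),
#   a(t+dt) = a(t) + dt/tau_A (r(t) - a(t)),
# explicit in t. `inputs` is ranks x (T-1); when f_R/f_F are NULL the
# pre-learning (novel) model is run. Teacher forcing replaces the model's own
# top-rank trace by `teacher_max` where supplied.
.forward_discrete <- function(inputs, n_bins, dt, transfer, k, tau_adapt,
                              w_R = 0, f_R = NULL, f_F = NULL,
                              init_rate = 0, teacher_max = NULL) {
  n_ranks <- nrow(inputs)
  stopifnot(ncol(inputs) >= n_bins - 1L)
  r <- matrix(0, n_ranks, n_bins)
  a <- matrix(0, n_ranks, n_bins)
  r[, 1L] <- init_rate
  a[, 1L] <- r[, 1L]
  learned <- !is.null(f_R)
  if (learned) stopifnot(length(f_R) == n_ranks, length(f_F) == n_ranks)
  for (t in seq_len(n_bins - 1L)) {
    r_max <- if (!is.null(teacher_max)) teacher_max[t] else r[n_ranks, t]
    tot <- w_R * mean(r[, t]) - k * a[, t] + inputs[, t]
    if (learned)
      tot <- tot + f_R * r_max + f_F * inputs[n_ranks, t]
    r[, t + 1L] <- phi(transfer, tot)
    a[, t + 1L] <- a[, t] + dt / tau_adapt * (r[, t] - a[, t])
  }
  list(rates = r, adaptation = a)
}

# Low-pass filter observed rates on the data grid, a(1) = r(1).
.lowpass_rates <- function(values, dt, tau_adapt) {
  a <- matrix(0, nrow(values), ncol(values))
  a[, 1L] <- values[, 1L]
  for (t in seq_len(ncol(values) - 1L))
    a[, t + 1L] <- a[, t] + dt / tau_adapt * (values[, t] - a[, t])
  a
}

#' Reconstruct external inputs from novel responses
#'
#' On the data grid the rate equation with \eqn{\tau_r = dt} reads
#' \eqn{r_i(t + dt) = \Phi(w_R \bar r(t) - k a_i(t) + I_i(t))}, so the
#' external input is recovered exactly from the novel responses alone:
#' \deqn{I_i(t) = \Phi^{-1}(r_i(t + dt)) - w_R \bar r(t) + k a_i(t),}
#' with \eqn{a_i} the low-pass filtered rate (time constant `tau_adapt`,
#' initialized at the first bin).
#'
#' @param novel a `"rank_time_matrix"` of novel responses.
#' @param transfer an invertible `"transfer_fun"` (linear or tabulated).
#' @param k adaptation strength.
#' @param tau_adapt adaptation time constant in ms.
#' @param w_R pre-learning recurrent strength (the fits use 0).
#' @return matrix ranks x (T-1) of inputs, defined for bins 1..T-1; attribute
#'   `"n_extrapolated"` counts rates outside a tabulated transfer's range.
#' @export
reconstruct_input <- function(novel, transfer = linear_transfer(), k = 1.8,
                              tau_adapt = 200, w_R = 0) {
  stopifnot(inherits(novel, "rank_time_matrix"))
  vals <- unclass(novel)
  dt <- attr(novel, "dt")
  n_bins <- ncol(vals)
  a <- .lowpass_rates(vals, dt, tau_adapt)
  inv <- phi_inverse(transfer, vals[, -1L, drop = FALSE])
  n_ex <- attr(inv, "n_extrapolated")
  rbar <- colMeans(vals)
  I <- inv - w_R * matrix(rbar[-n_bins], nrow(vals), n_bins - 1L,
                          byrow = TRUE) +
    k * a[, -n_bins, drop = FALSE]
  attr(I, "n_extrapolated") <- n_ex
  I
}

#' Fit the post-synaptic dependence of synaptic plasticity
#'
#' The central model fit: given rank-averaged novel and familiar response
#' matrices, the external inputs are first reconstructed from the novel
#' responses; then, with a one-hot pre-synaptic dependence on the top rank
#' (g = 1 for the preferred stimulus, 0 otherwise), each rank's familiar
#' response obeys
#' \deqn{\Phi^{-1}(r_i^{fam}(t+dt)) - w_R \bar r^{fam}(t) + k a_i^{fam}(t)
#'   - I_i(t) = f_{R,i}\, r_{max}^{fam}(t) + f_{F,i}\, I_{max}(t),}
#' a two-parameter weighted linear regression per rank (teacher forcing: the
#' measured top-rank familiar trace and the reconstructed top-rank input serve
#' as regressors). Late bins (>= `late_onset` ms) get weight `late_weight` to
#' capture the rebound.
#'
#' @param novel,familiar `"rank_time_matrix"` objects on the same grid.
#' @param transfer an invertible `"transfer_fun"`.
#' @param k adaptation strength.
#' @param tau_adapt adaptation time constant (ms).
#' @param w_R pre-learning recurrent strength.
#' @param late_weight weight applied to late bins.
#' @param late_onset start of the late window in ms after stimulus onset.
#' @return object of class `"plasticity_fit"` with components
#'   `coefficients` (data.frame: rank, f_R, f_F), `residuals` (ranks x (T-1)),
#'   `weighted_sse` (per rank), `weights`, `inputs`, `novel`, `familiar`,
#'   `transfer` and the fit parameters. Methods: `print`, `summary`, `coef`,
#'   `fitted`, `residuals`, `predict`, `plot`, `simulate`.
#' @seealso [reconstruct_input()], [synthesize_dataset()], [derive_transfer()]
#' @export
fit_plasticity <- function(novel, familiar, transfer = linear_transfer(),
                           k = 1.8, tau_adapt = 200, w_R = 0,
                           late_weight = 5, late_onset = 230) {
  stopifnot(inherits(novel, "rank_time_matrix"),
            inherits(familiar, "rank_time_matrix"),
            nrow(novel) == nrow(familiar), ncol(novel) == ncol(familiar),
            attr(novel, "dt") == attr(familiar, "dt"))
  n_ranks <- nrow(novel)
  n_bins <- ncol(novel)
  dt <- attr(novel, "dt")
  tm <- bin_times(novel)

  I <- reconstruct_input(novel, transfer, k = k, tau_adapt = tau_adapt,
                         w_R = w_R)
  fam <- unclass(familiar)
  a_fam <- .lowpass_rates(fam, dt, tau_adapt)
  rbar_fam <- colMeans(fam)

  y <- phi_inverse(transfer, fam[, -1L, drop = FALSE]) -
    w_R * matrix(rbar_fam[-n_bins], n_ranks, n_bins - 1L, byrow = TRUE) +
    k * a_fam[, -n_bins, drop = FALSE] - I
  x_rmax <- fam[n_ranks, -n_bins]        # measured top-rank familiar trace
  x_imax <- I[n_ranks, ]                 # reconstructed top-rank input
  X <- cbind(r_max = x_rmax, I_max = x_imax)
  w <- ifelse(tm[-n_bins] >= late_onset, late_weight, 1)

  f_R <- f_F <- rep(NA_real_, n_ranks)
  resid <- matrix(NA_real_, n_ranks, n_bins - 1L)
  wsse <- rep(NA_real_, n_ranks)
  deficient <- integer(0)
  Xw <- X * sqrt(w)
  if (qr(Xw)$rank < 2L) {
    deficient <- seq_len(n_ranks)
    warning("design is rank-deficient (top-rank trace collinear with its ",
            "input) for all ranks; coefficients are NA")
  } else {
    for (i in seq_len(n_ranks)) {
      fit <- stats::lm.wfit(X, y[i, ], w)
      f_R[i] <- fit$coefficients[["r_max"]]
      f_F[i] <- fit$coefficients[["I_max"]]
      resid[i, ] <- fit$residuals
      wsse[i] <- sum(w * fit$residuals^2)
    }
  }

  structure(list(
    coefficients = data.frame(rank = seq_len(n_ranks), f_R = f_R, f_F = f_F),
    residuals = resid, weighted_sse = wsse, weights = w,
    inputs = I, novel = novel, familiar = familiar, transfer = transfer,
    k = k, tau_adapt = tau_adapt, w_R = w_R,
    late_weight = late_weight, late_onset = late_onset,
    deficient_ranks = deficient,
    call = match.call()),
    class = "plasticity_fit")
}

#' @export
coef.plasticity_fit <- function(object, ...) {
  out <- as.matrix(object$coefficients[, c("f_R", "f_F")])
  rownames(out) <- object$coefficients$rank
  out
}

#' @export
residuals.plasticity_fit <- function(object, ...) object$residuals

#' @export
fitted.plasticity_fit <- function(object, ...) {
  predict(object)
}

#' Predict familiar responses from a plasticity fit
#'
#' Teacher-forced one-step-ahead prediction: bins 2..T of the familiar matrix
#' are predicted from the measured familiar state at the previous bin and the
#' fitted per-rank coefficients; bin 1 is copied from the data.
#'
#' @param object a `"plasticity_fit"`.
#' @param ... unused.
#' @return a `"rank_time_matrix"` of predicted familiar responses.
#' @export
predict.plasticity_fit <- function(object, ...) {
  fam <- unclass(object$familiar)
  n_bins <- ncol(fam)
  dt <- attr(object$familiar, "dt")
  a_fam <- .lowpass_rates(fam, dt, object$tau_adapt)
  rbar <- colMeans(fam)
  f_R <- object$coefficients$f_R
  f_F <- object$coefficients$f_F
  pred <- fam
  for (t in seq_len(n_bins - 1L)) {
    tot <- object$w_R * rbar[t] + f_R * fam[nrow(fam), t] -
      object$k * a_fam[, t] + object$inputs[, t] +
      f_F * object$inputs[nrow(fam), t]
    pred[, t + 1L] <- phi(object$transfer, tot)
  }
  rank_time_matrix(pred, dt = dt,
                   onset_index = attr(object$familiar, "onset_index"),
                   condition = "familiar (predicted)")
}

#' Free-running simulation from a plasticity fit
#'
#' Regenerates familiar response matrices from the fitted coefficients and the
#' reconstructed inputs, letting the top-rank trace drive itself (no teacher
#' forcing), optionally adding Gaussian observation noise.
#'
#' @param object a `"plasticity_fit"`.
#' @param nsim number of simulated datasets.
#' @param seed optional RNG seed.
#' @param noise_sd observation noise standard deviation.
#' @param ... unused.
#' @return a list of `nsim` `"rank_time_matrix"` objects.
#' @export
simulate.plasticity_fit <- function(object, nsim = 1, seed = NULL,
                                    noise_sd = 0, ...) {
  if (!is.null(seed)) set.seed(seed)
  fam <- unclass(object$familiar)
  dt <- attr(object$familiar, "dt")
  base <- .forward_discrete(object$inputs, ncol(fam), dt, object$transfer,
                            k = object$k, tau_adapt = object$tau_adapt,
                            w_R = object$w_R,
                            f_R = object$coefficients$f_R,
                            f_F = object$coefficients$f_F,
                            init_rate = fam[, 1L])$rates
  lapply(seq_len(nsim), function(s) {
    v <- base
    if (noise_sd > 0) v <- v + stats::rnorm(length(v), sd = noise_sd)
    rank_time_matrix(v, dt = dt,
                     onset_index = attr(object$familiar, "onset_index"),
                     condition = "familiar (simulated)")
  })
}

#' @export
print.plasticity_fit <- function(x, ...) {
  cat("Post-synaptic plasticity dependence fit\n")
  cat(sprintf("  %d ranks x %d bins (dt = %g ms), k = %g, tau_A = %g ms, w_R = %g\n",
              nrow(x$novel), ncol(x$novel), attr(x$novel, "dt"),
              x$k, x$tau_adapt, x$w_R))
  cat(sprintf("  mean f_R = %.4g (recurrent), mean f_F = %.4g (feedforward)\n",
              mean(x$coefficients$f_R), mean(x$coefficients$f_F)))
  if (length(x$deficient_ranks))
    cat("  rank-deficient design; coefficients are NA\n")
  invisible(x)
}

#' @export
summary.plasticity_fit <- function(object, ...) {
  co <- object$coefficients
  rho <- suppressWarnings(
    stats::cor(co$rank, co$f_R, method = "spearman", use = "complete.obs"))
  out <- list(n_ranks = nrow(co), n_bins = ncol(object$novel),
              mean_f_R = mean(co$f_R), mean_f_F = mean(co$f_F),
              top_f_R = co$f_R[nrow(co)],
              spearman_f_R_rank = rho,
              total_weighted_sse = sum(object$weighted_sse),
              deficient_ranks = object$deficient_ranks)
  class(out) <- "summary.plasticity_fit"
  out
}

#' @export
print.summary.plasticity_fit <- function(x, ...) {
  cat("Summary of plasticity-dependence fit\n")
  cat(sprintf("  ranks: %d, bins: %d\n", x$n_ranks, x$n_bins))
  cat(sprintf("  mean f_R: %.4g   mean f_F: %.4g   top-rank f_R: %.4g\n",
              x$mean_f_R, x$mean_f_F, x$top_f_R))
  cat(sprintf("  Spearman rho(f_R, rank): %.3f\n", x$spearman_f_R_rank))
  cat(sprintf("  total weighted SSE: %.6g\n", x$total_weighted_sse))
  invisible(x)
}

#' @export
plot.plasticity_fit <- function(x, ...) {
  co <- x$coefficients
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(co$rank, co$f_R, type = "p", pch = 16, cex = 0.6,
       xlab = "stimulus rank", ylab = expression(f[R]),
       main = "recurrent", ...)
  graphics::abline(h = 0, lty = 3)
  plot(co$rank, co$f_F, type = "p", pch = 16, cex = 0.6,
       xlab = "stimulus rank", ylab = expression(f[F]),
       main = "feedforward", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Derive a tabulated transfer function from novel time-averaged responses
#'
#' Assuming the synaptic inputs across stimuli are Gaussian and the f-I curve
#' monotone, the curve is recovered by quantile matching: rank i's
#' time-averaged novel response (window 75-200 ms by default) is paired with
#' the standard-normal quantile at probability (i - 0.5)/n. Rate-order
#' violations are cleaned up isotonically before tabulation.
#'
#' @param novel a `"rank_time_matrix"` of novel responses, or a numeric vector
#'   of per-rank time-averaged responses (ascending rank order).
#' @param window ms window for the time average when `novel` is a matrix.
#' @return a tabulated `"transfer_fun"`.
#' @export
derive_transfer <- function(novel, window = c(75, 200)) {
  if (inherits(novel, "rank_time_matrix")) {
    tm <- bin_times(novel)
    sel <- which(tm >= window[1L] & tm <= window[2L])
    if (!length(sel)) stop("averaging window contains no bins")
    means <- rowMeans(unclass(novel)[, sel, drop = FALSE])
  } else {
    means <- as.numeric(novel)
  }
  n <- length(means)
  if (n < 3L) stop("need at least 3 ranks to derive a transfer function")
  q <- stats::qnorm((seq_len(n) - 0.5) / n)
  iso <- stats::isoreg(seq_len(n), means)$yf
  tabulated_transfer(input = q, rate = iso)
}
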