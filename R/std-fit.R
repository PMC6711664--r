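#' Fit the reduced short-term-depression model to maximal-response traces
#'
#' Tests whether synaptic depression can replace firing-rate adaptation as the
#' negative feedback behind the familiar-stimulus oscillation. The input
#' \eqn{I_M(t)} is obtained from the novel maximal-response trace via the
#' reduced model's own pre-learning equation (recurrent coupling negligible
#' before learning and \eqn{\tau_r = dt}, so \eqn{I_M(t) = r^{nov}(t + dt)});
#' the learned strength \eqn{\overline{fg} = f^R_m g^R_m} and the depletion
#' rate \eqn{\gamma} are then chosen to minimize the sum of squared errors
#' between the free-running reduced model
#' \deqn{r(t+dt) = \overline{fg}\, x(t) r(t) + I_M(t), \quad
#'   x(t+dt) = x(t) + dt\{(1 - x)/\tau_x - \gamma x r\}}
#' and the familiar maximal-response trace. The optimizer is deterministic: a
#' fixed log-spaced grid followed by Nelder-Mead refinement in log-parameter
#' space.
#'
#' @param novel_max,familiar_max numeric time series on a common grid (or
#'   single-row `"rank_time_matrix"` objects).
#' @param dt bin width in ms.
#' @param tau_rate rate time constant (equal to `dt` on the data grid).
#' @param tau_recover resource recovery time constant \eqn{\tau_x} in ms.
#' @param fg_range,gamma_range search ranges (log-spaced grid bounds).
#' @param grid_n grid points per axis.
#' @param gamma_fixed optionally pin \eqn{\gamma} (e.g. 0 for the pure
#'   linear-gain fit) and optimize `fg` alone.
#' @return object of class `"std_fit"`: list with `fg_strength`,
#'   `depletion_strength`, `loss`, `fitted` (predicted familiar trace),
#'   `input`, `novel_max`, `familiar_max`, `dt`, `tau_recover`.
#' @export
fit_std <- function(novel_max, familiar_max, dt = 5, tau_rate = dt,
                    tau_recover = 200,
                    fg_range = c(0.05, 8), gamma_range = c(1e-4, 1),
                    grid_n = 60, gamma_fixed = NULL) {
  as_trace <- function(x) {
    if (inherits(x, "rank_time_matrix")) as.numeric(unclass(x)[1L, ])
    else as.numeric(x)
  }
  r_nov <- as_trace(novel_max)
  r_fam <- as_trace(familiar_max)
  stopifnot(length(r_nov) == length(r_fam), length(r_nov) >= 3L,
            all(is.finite(r_nov)), all(is.finite(r_fam)),
            dt > 0, tau_recover > 0)
  n_bins <- length(r_nov)
  I <- r_nov[-1L]                       # I_M(t) = r_nov(t + dt)

  predict_trace <- function(fg, gamma) {
    r <- r_fam[1L]
    x <- 1 / (1 + gamma * tau_recover * max(r, 0))
    out <- numeric(n_bins)
    out[1L] <- r
    for (t in seq_len(n_bins - 1L)) {
      r_new <- fg * x * r + I[t]
      x <- .std_resource_step(x, r, dt, tau_recover, gamma)
      r <- r_new
      out[t + 1L] <- r
    }
    out
  }
  loss_fn <- function(fg, gamma) {
    pred <- predict_trace(fg, gamma)
    if (any(!is.finite(pred))) return(Inf)
    sum((pred - r_fam)[-1L]^2)
  }

  if (is.null(gamma_fixed)) {
    fg_grid <- exp(seq(log(fg_range[1L]), log(fg_range[2L]), length.out = grid_n))
    ga_grid <- exp(seq(log(gamma_range[1L]), log(gamma_range[2L]),
                       length.out = grid_n))
    best <- c(NA_real_, NA_real_); best_loss <- Inf
    for (fg in fg_grid) for (ga in ga_grid) {
      l <- loss_fn(fg, ga)
      if (l < best_loss) { best_loss <- l; best <- c(fg, ga) }
    }
    opt <- stats::optim(log(best),
                        function(p) loss_fn(exp(p[1L]), exp(p[2L])),
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    fg_hat <- exp(opt$par[1L]); ga_hat <- exp(opt$par[2L])
    loss <- opt$value
  } else {
    stopifnot(gamma_fixed >= 0)
    fg_grid <- exp(seq(log(fg_range[1L]), log(fg_range[2L]),
                       length.out = grid_n))
    losses <- vapply(fg_grid, loss_fn, numeric(1L), gamma = gamma_fixed)
    best <- fg_grid[which.min(losses)]
    opt <- stats::optim(log(best),
                        function(p) loss_fn(exp(p), gamma_fixed),
                        method = "Brent",
                        lower = log(fg_range[1L]) - 2,
                        upper = log(fg_range[2L]) + 2)
    fg_hat <- exp(opt$par); ga_hat <- gamma_fixed
    loss <- opt$value
  }

  structure(list(fg_strength = fg_hat, depletion_strength = ga_hat,
                 loss = loss, fitted = predict_trace(fg_hat, ga_hat),
                 input = I, novel_max = r_nov, familiar_max = r_fam,
                 dt = dt, tau_recover = tau_recover),
            class = "std_fit")
}

#' @export
coef.std_fit <- function(object, ...) {
  c(fg_strength = object$fg_strength,
    depletion_strength = object$depletion_strength)
}

#' @export
print.std_fit <- function(x, ...) {
  cat("Reduced short-term-depression model fit\n")
  cat(sprintf("  fg strength (f_m g_m): %.4g\n", x$fg_strength))
  cat(sprintf("  depletion strength (gamma): %.4g\n", x$depletion_strength))
  cat(sprintf("  SSE: %.6g over %d bins (dt = %g ms, tau_x = %g ms)\n",
              x$loss, length(x$familiar_max), x$dt, x$tau_recover))
  invisible(x)
}

#' @export
fitted.std_fit <- function(object, ...) object$fitted

#' @export
residuals.std_fit <- function(object, ...) object$familiar_max - object$fitted

#' @export
plot.std_fit <- function(x, ...) {
  tm <- (seq_along(x$familiar_max) - 1L) * x$dt
  graphics::matplot(tm, cbind(x$familiar_max, x$fitted), type = "l",
                    lty = c(1, 2), col = c("black", "firebrick"),
                    xlab = "time (ms)", ylab = "maximal response", ...)
  graphics::legend("topright", c("familiar (data)", "STD model fit"),
                   lty = c(1, 2), col = c("black", "firebrick"), bty = "n")
  invisible(x)
}
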