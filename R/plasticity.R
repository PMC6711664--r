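#' Separable synaptic plasticity rule
#'
#' A one-shot weight update factorizing into post- and pre-synaptic
#' dependences, \eqn{\Delta W_{ij} = f(\xi_i) g(\xi_j) / N} (the 1/N factor is
#' controlled by `normalize_by_n`; it is conventionally on for recurrent
#' updates and off for feedforward ones). With a zero-sum pre-dependence
#' \eqn{\sum_j g(\xi_j) = 0} the update preserves each row's total weight.
#'
#' @param post_dependence per-unit post-synaptic values \eqn{f(\xi_i)}.
#' @param pre_dependence per-unit pre-synaptic values \eqn{g(\xi_j)}.
#' @param normalize_by_n logical; divide the outer product by N.
#' @param zero_sum assert that `pre_dependence` sums to zero (within 1e-12
#'   relative to its scale).
#' @return an object of class `"separable_rule"`.
#' @export
separable_rule <- function(post_dependence, pre_dependence,
                           normalize_by_n = TRUE, zero_sum = FALSE) {
  if (length(post_dependence) != length(pre_dependence))
    stop("post and pre dependence vectors must have equal length")
  if (zero_sum) {
    s <- sum(pre_dependence)
    tol <- 1e-12 * max(1, sum(abs(pre_dependence)))
    if (abs(s) > tol)
      stop("pre_dependence does not sum to zero (sum = ", s, ")")
  }
  structure(list(post_dependence = post_dependence,
                 pre_dependence = pre_dependence,
                 normalize_by_n = normalize_by_n),
            class = "separable_rule")
}

#' Weight update induced by a separable rule
#'
#' @param rule a [separable_rule()].
#' @return the rank-1 update matrix \eqn{\Delta W_{ij} = f_i g_j} (divided by
#'   N when the rule is N-normalized).
#' @export
separable_delta <- function(rule) {
  stopifnot(inherits(rule, "separable_rule"))
  n <- length(rule$post_dependence)
  d <- outer(rule$post_dependence, rule$pre_dependence)
  if (rule$normalize_by_n) d <- d / n
  d
}

#' Hebbian recurrent update
#'
#' The covariance-style Hebbian rule
#' \deqn{\Delta W^R_{ij} = \frac{\alpha}{N\,\mathrm{var}(\xi)}\,
#'   \xi_i (\xi_j - \bar\xi),}
#' where the variance is the population (1/N) variance. This normalization
#' makes the induced mean-field potentiation exactly
#' \eqn{\overline{fg}_R = \alpha}, since
#' \eqn{\mathrm{mean}(\xi(\xi - \bar\xi)) = \mathrm{var}(\xi)}.
#'
#' @param selectivity activity pattern \eqn{\xi} (must be non-constant).
#' @param strength plasticity strength \eqn{\alpha}.
#' @param as_rule return the underlying [separable_rule()] instead of the
#'   matrix.
#' @return the N x N update matrix (rows sum exactly to 0), or the rule.
#' @export
hebbian_delta <- function(selectivity, strength, as_rule = FALSE) {
  n <- length(selectivity)
  v <- mean(selectivity^2) - mean(selectivity)^2   # population variance
  if (v <= 0) stop("selectivity is constant: zero variance")
  rule <- separable_rule(post_dependence = strength * selectivity / v,
                         pre_dependence = selectivity - mean(selectivity),
                         normalize_by_n = TRUE, zero_sum = TRUE)
  if (as_rule) rule else separable_delta(rule)
}

#' Mean-field coefficients induced by separable plasticity
#'
#' Computes the population averages that parameterize the reduced dynamics:
#' \eqn{\bar f_{R,F} = \mathrm{mean}(f_{R,F})},
#' \eqn{\overline{fg}_{R,F} = \mathrm{mean}(f_{R,F}\, g_R)}, and the drive
#' projections \eqn{\bar I = \mathrm{mean}(I_i)},
#' \eqn{I_M = \mathrm{mean}(g_R I_i)}, \eqn{I_F = \mathrm{mean}(g_F I_i)}.
#'
#' @param recurrent a [separable_rule()] for the recurrent update.
#' @param feedforward optional [separable_rule()] for the feedforward update;
#'   when `NULL` the feedforward coefficients are zero.
#' @param selectivity unused placeholder kept for signature clarity; the rule
#'   vectors already carry the \eqn{\xi}-dependence.
#' @param external_input optional per-unit drive amplitudes \eqn{I_i} (the
#'   time-varying waveform factors out).
#' @return list of class `"meanfield_coefficients"` with fields `fbar_R`,
#'   `fbar_F`, `fgbar_R`, `fgbar_F`, `input_mean`, `input_m`, `input_f`.
#' @export
meanfield_coefficients <- function(recurrent, feedforward = NULL,
                                   selectivity = NULL, external_input = NULL) {
  stopifnot(inherits(recurrent, "separable_rule"))
  fR <- recurrent$post_dependence
  gR <- recurrent$pre_dependence
  if (!is.null(feedforward)) {
    stopifnot(inherits(feedforward, "separable_rule"),
              length(feedforward$post_dependence) == length(fR))
    fF <- feedforward$post_dependence
    gF <- feedforward$pre_dependence
  } else {
    fF <- numeric(length(fR)); gF <- numeric(length(fR))
  }
  out <- list(fbar_R = mean(fR), fbar_F = mean(fF),
              fgbar_R = mean(fR * gR), fgbar_F = mean(fF * gR),
              input_mean = NA_real_, input_m = NA_real_, input_f = NA_real_)
  if (!is.null(external_input)) {
    stopifnot(length(external_input) == length(fR))
    out$input_mean <- mean(external_input)
    out$input_m <- mean(gR * external_input)
    out$input_f <- mean(gF * external_input)
  }
  structure(out, class = "meanfield_coefficients")
}

#' @export
print.meanfield_coefficients <- function(x, ...) {
  cat("Mean-field coefficients:\n")
  cat(sprintf("  fbar_R = %.6g  fbar_F = %.6g\n", x$fbar_R, x$fbar_F))
  cat(sprintf("  fgbar_R = %.6g  fgbar_F = %.6g\n", x$fgbar_R, x$fgbar_F))
  if (is.finite(x$input_mean))
    cat(sprintf("  input_mean = %.6g  input_m = %.6g  input_f = %.6g\n",
                x$input_mean, x$input_m, x$input_f))
  invisible(x)
}

#' Orthogonalize a second selectivity pattern against a first
#'
#' For two-stimulus learning the updates add, and their cross mean-field
#' terms vanish when the patterns are empirically uncorrelated,
#' \eqn{\mathrm{cov}(\xi^1, \xi^2) = 0}. This removes the empirical
#' cross-projection of `pattern` on `reference` so that condition holds
#' exactly at finite N.
#'
#' @param pattern the pattern to adjust (\eqn{\xi^2}).
#' @param reference the fixed pattern (\eqn{\xi^1}).
#' @return adjusted `pattern` with zero empirical covariance with `reference`.
#' @export
orthogonalize_selectivity <- function(pattern, reference) {
  stopifnot(length(pattern) == length(reference))
  cr <- reference - mean(reference)
  v <- mean(cr^2)
  if (v <= 0) stop("reference pattern is constant")
  pattern - mean(cr * pattern) / v * cr
}
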