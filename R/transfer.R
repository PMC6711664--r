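#' Static transfer functions (f-I curves)
#'
#' A transfer function maps total synaptic input to firing rate. Three kinds
#' are supported: the identity (`linear_transfer()`), used throughout the
#' mean-field analysis; a shifted rectification (`rectified_transfer()`),
#' used for the competition model where \eqn{\Phi(x) = x} for \eqn{x \ge}
#' `threshold` and 0 otherwise; and a tabulated monotone curve
#' (`tabulated_transfer()`) derived from data, invertible on the convex hull
#' of its rate samples with linear extrapolation beyond it.
#'
#' @param threshold input value below which the rectified transfer returns 0.
#' @param input,rate paired samples of a monotone nondecreasing f-I curve.
#' @return An object of class `"transfer_fun"`.
#' @examples
#' phi(linear_transfer(), c(-1, 0, 2))
#' phi(rectified_transfer(-3), c(-4, -2, 1))
#' tf <- tabulated_transfer(input = c(-1, 0, 1), rate = c(0, 1, 3))
#' phi_inverse(tf, phi(tf, 0.25))
#' @export
linear_transfer <- function() {
  structure(list(kind = "linear"), class = "transfer_fun")
}

#' @rdname linear_transfer
#' @export
rectified_transfer <- function(threshold = 0) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, is.finite(threshold))
  structure(list(kind = "shifted_rectified", threshold = threshold),
            class = "transfer_fun")
}

#' @rdname linear_transfer
#' @export
tabulated_transfer <- function(input, rate) {
  stopifnot(length(input) == length(rate), length(input) >= 2L,
            all(is.finite(input)), all(is.finite(rate)))
  ord <- order(input)
  input <- input[ord]; rate <- rate[ord]
  if (any(diff(input) <= 0))
    stop("tabulated transfer requires strictly increasing input samples")
  if (any(diff(rate) < 0))
    stop("tabulated transfer must be monotone nondecreasing in rate")
  structure(list(kind = "tabulated_monotone", input = input, rate = rate),
            class = "transfer_fun")
}

# monotone piecewise-linear interpolation with linear extrapolation at the ends
.interp_extrap <- function(x, y, xout) {
  n <- length(x)
  d <- dim(xout)
  xout <- as.vector(xout)
  out <- stats::approx(x, y, xout = xout, rule = 2, ties = "ordered")$y
  lo <- xout < x[1L]
  hi <- xout > x[n]
  if (any(lo)) {
    s <- (y[2L] - y[1L]) / (x[2L] - x[1L])
    out[lo] <- y[1L] + s * (xout[lo] - x[1L])
  }
  if (any(hi)) {
    s <- (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
    out[hi] <- y[n] + s * (xout[hi] - x[n])
  }
  dim(out) <- d
  out
}

#' Evaluate or invert a transfer function
#'
#' `phi()` maps input to rate; `phi_inverse()` maps rate back to input.
#' Only the linear and tabulated kinds are invertible; for the tabulated kind,
#' rates outside the table are linearly extrapolated and the number of
#' extrapolated points is attached as attribute `"n_extrapolated"`.
#'
#' @param transfer a `"transfer_fun"` object.
#' @param x numeric vector of inputs (for `phi`) or rates (for `phi_inverse`).
#' @return numeric vector of the same length as `x`.
#' @export
phi <- function(transfer, x) {
  stopifnot(inherits(transfer, "transfer_fun"))
  switch(transfer$kind,
    linear = x,
    shifted_rectified = ifelse(x >= transfer$threshold, x, 0),
    tabulated_monotone = .interp_extrap(transfer$input, transfer$rate, x),
    stop("unknown transfer kind: ", transfer$kind)
  )
}

#' @rdname phi
#' @export
phi_inverse <- function(transfer, x) {
  stopifnot(inherits(transfer, "transfer_fun"))
  switch(transfer$kind,
    linear = x,
    shifted_rectified =
      stop("the shifted-rectified transfer is not invertible"),
    tabulated_monotone = {
      rate <- transfer$rate
      if (any(diff(rate) <= 0)) {
        # flat segments break invertibility; keep strictly increasing knots
        keep <- c(TRUE, diff(rate) > 0)
        rate <- rate[keep]
        inp <- transfer$input[keep]
      } else inp <- transfer$input
      out <- .interp_extrap(rate, inp, x)
      n_ex <- sum(x < rate[1L] | x > rate[length(rate)])
      attr(out, "n_extrapolated") <- n_ex
      out
    },
    stop("unknown transfer kind: ", transfer$kind)
  )
}

#' @export
print.transfer_fun <- function(x, ...) {
  cat("Transfer function (f-I curve), kind:", x$kind, "\n")
  if (x$kind == "shifted_rectified")
    cat("  threshold:", x$threshold, "\n")
  if (x$kind == "tabulated_monotone")
    cat("  ", length(x$input), "tabulated points, rate range [",
        min(x$rate), ",", max(x$rate), "]\n")
  invisible(x)
}
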