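#' Filter specification
#'
#' Zero-phase low-pass Butterworth specification: an even single-pass order and
#' a cutoff in hertz, applied forward and backward (two passes). Note the
#' forward-backward application squares the single-pass magnitude response, so
#' the gain at the cutoff frequency is 0.5, not 1/sqrt(2).
#'
#' @param cutoff Cutoff frequency, Hz.
#' @param order Single-pass filter order (even; default 4).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(cutoff, order = 4L) {
  if (order < 2 || order %% 2 != 0) stop("filter order must be even and >= 2")
  if (cutoff <= 0) stop("cutoff must be > 0")
  structure(list(order = as.integer(order), cutoff = cutoff, passes = 2L),
            class = "filter_spec")
}

# Polynomial coefficients (ascending powers of z^-1) from roots.
.poly_from_roots <- function(r) {
  c <- 1 + 0i
  for (ri in r) c <- c(c, 0) - ri * c(0, c)
  c
}

# Digital low-pass Butterworth via bilinear transform with frequency
# prewarping; returns coefficients b, a with a[1] = 1 and unit DC gain.
.butter_lowpass <- function(order, cutoff, rate) {
  wc <- 2 * rate * tan(pi * cutoff / rate)
  k <- seq_len(order)
  p <- wc * exp(1i * pi * (2 * k + order - 1) / (2 * order)) # analog poles
  pd <- (2 * rate + p) / (2 * rate - p)                      # digital poles
  a <- Re(.poly_from_roots(pd))
  b <- Re(.poly_from_roots(rep(-1 + 0i, order)))             # zeros at z = -1
  b <- b * (sum(a) / sum(b))
  list(b = b / a[1], a = a / a[1])
}

# Causal IIR filter with zero initial state, vectorized through stats::filter.
.iir <- function(b, a, x) {
  n <- length(x)
  xp <- c(rep(0, length(b) - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[length(b) - 1 + seq_len(n)]
  as.numeric(stats::filter(v, -a[-1], method = "recursive"))
}

#' Zero-phase low-pass Butterworth filter
#'
#' Applies the specified Butterworth low-pass filter forward and backward
#' (zero phase, no event time shift). Edges are handled by odd reflection of
#' `3 * order` samples plus a constant settling run that anchors the filter
#' state at the endpoint value, so a constant series passes through unchanged
#' (exact DC gain 1).
#'
#' @param x Numeric vector, or matrix/data frame filtered column-wise.
#' @param rate Sampling rate, Hz. Must exceed `2 * cutoff`.
#' @param spec A [filter_spec()]; default 4th order.
#' @param cutoff Shorthand: if `spec` is missing, build `filter_spec(cutoff)`.
#' @return Filtered series, same shape and time base as the input.
#' @export
lowpass <- function(x, rate, spec = filter_spec(cutoff), cutoff = NULL) {
  if (is.matrix(x) || is.data.frame(x)) {
    out <- as.matrix(x)
    for (j in seq_len(ncol(out))) out[, j] <- lowpass(out[, j], rate, spec)
    return(out)
  }
  if (rate <= 2 * spec$cutoff)
    stop("cutoff must be below the Nyquist frequency of the stream")
  n <- length(x)
  if (n < 3 * spec$order) stop("insufficient samples for filtering")
  ba <- .butter_lowpass(spec$order, spec$cutoff, rate)
  pad <- min(3 * spec$order, n - 1L)
  settle <- max(64L, ceiling(15 * rate / spec$cutoff))
  head_refl <- 2 * x[1] - x[seq(pad + 1, 2)]
  tail_refl <- 2 * x[n] - x[seq(n - 1, n - pad)]
  ext <- c(rep(head_refl[1], settle), head_refl, x, tail_refl,
           rep(tail_refl[pad], settle))
  y <- .iir(ba$b, ba$a, ext)
  y <- rev(.iir(ba$b, ba$a, rev(y)))
  y[settle + pad + seq_len(n)]
}
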