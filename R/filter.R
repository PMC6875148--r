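#' Least-squares linear-phase FIR bandpass design
#'
#' Designs a Type-I (odd-length, even-symmetric) linear-phase FIR filter by
#' weighted least squares on a dense frequency grid. The desired amplitude is
#' 0 on `[0, low/2]`, 1 on `[low, high]`, and 0 on `[(high + nyquist)/2,
#' nyquist]`; the transition bands are unconstrained. An exact DC zero is
#' imposed as an equality constraint so constant (and mean) components are
#' removed. Stopbands are weighted 10:1 relative to the passband.
#'
#' @param tr sampling interval, seconds.
#' @param low,high band edges, Hz; `low < high < 1/(2*tr)`.
#' @param n_taps odd filter length (default 65 taps, the longest odd length
#'   at or below a third of a 240-volume series).
#' @param grid_n frequency-grid points for the least-squares fit.
#' @return numeric vector of `n_taps` coefficients with attributes `tr`,
#'   `band`, `n_taps`.
#' @export
design_bandpass_fir <- function(tr, low = 0.01, high = 0.1, n_taps = 65,
                                grid_n = 1024) {
  nyq <- 1 / (2 * tr)
  if (!(low > 0 && low < high && high < nyq))
    stop(sprintf("need 0 < low < high < Nyquist = %g Hz", nyq))
  if (n_taps %% 2L == 0L) stop("n_taps must be odd (Type-I linear phase)")
  M <- (n_taps - 1L) %/% 2L
  # band edges in cycles/sample
  e <- c(0, low / 2, low, high, (high + nyq) / 2, nyq) * tr
  f <- seq(0, 0.5, length.out = grid_n)
  in_stop <- f <= e[2] | f >= e[5]
  in_pass <- f >= e[3] & f <= e[4]
  # desired amplitude: 0 in stopbands, 1 in passband, linear ramps across the
  # transition bands, which enter at low weight only to condition the fit
  d <- numeric(length(f))
  d[in_pass] <- 1
  lo_tr <- f > e[2] & f < e[3]
  hi_tr <- f > e[4] & f < e[5]
  d[lo_tr] <- (f[lo_tr] - e[2]) / (e[3] - e[2])
  d[hi_tr] <- (e[5] - f[hi_tr]) / (e[5] - e[4])
  w <- ifelse(in_pass, 1, ifelse(in_stop, 30, 0.02))
  # amplitude basis: A(f) = g0 + sum_k 2 g_k cos(2 pi f k)
  B <- cbind(1, 2 * cos(2 * pi * outer(f, seq_len(M))))
  a0 <- c(1, rep(2, M))                       # A(0) in the same basis
  BtWB <- crossprod(B * sqrt(w))
  BtWd <- crossprod(B, w * d)
  kkt <- rbind(cbind(2 * BtWB, a0), c(a0, 0))
  sol <- solve(kkt, c(2 * BtWd, 0))
  g <- sol[seq_len(M + 1L)]
  h <- c(rev(g[-1]), g[1], g[-1])             # symmetric impulse response
  structure(h, tr = tr, band = c(low, high), n_taps = n_taps)
}

#' Amplitude response of an FIR filter
#'
#' @param h FIR coefficients.
#' @param freq_hz frequencies at which to evaluate, Hz.
#' @param tr sampling interval, seconds (default from the filter's attribute).
#' @return modulus of the frequency response at `freq_hz`.
#' @export
fir_response <- function(h, freq_hz, tr = attr(h, "tr")) {
  k <- seq_along(h) - 1
  vapply(freq_hz * tr, function(f)
    Mod(sum(h * exp(-2i * pi * f * k))), 0)
}

#' Bandpass-filter a region series stack
#'
#' Applies the least-squares linear-phase FIR bandpass to every region series
#' of every subject. Edges are reflect-padded by one filter length and the
#' group delay (`(n_taps-1)/2` samples) is compensated, so the output is
#' aligned with the input and has the input's length. The same filter is used
#' for all subjects and regions.
#'
#' @param stack a `region_series_stack`.
#' @param low,high band edges, Hz; defaults 0.01 and 0.1.
#' @param n_taps odd filter length, default 65.
#' @return the stack with filtered series, `filtered = TRUE` and `band` set.
#' @export
bandpass_fir <- function(stack, low = 0.01, high = 0.1, n_taps = 65) {
  stopifnot(inherits(stack, "region_series_stack"))
  n <- nrow(stack$series[[1]])
  if (n < 3L * n_taps)
    stop(sprintf("length error: %d volumes but >= %d required for a %d-tap filter",
                 n, 3L * n_taps, n_taps))
  h <- design_bandpass_fir(stack$tr, low, high, n_taps)
  out <- stack
  out$series <- lapply(stack$series, function(Y) {
    apply(Y, 2, apply_fir_reflect, h = h)
  })
  for (s in seq_along(out$series)) colnames(out$series[[s]]) <-
    colnames(stack$series[[s]])
  out$filtered <- TRUE
  out$band <- c(low, high)
  out$filter <- h
  out
}

# Zero-phase application of a symmetric odd-length FIR via reflect padding
# and centred convolution.
apply_fir_reflect <- function(x, h) {
  L <- length(h)
  n <- length(x)
  xp <- c(rev(x[2:(L + 1)]), x, rev(x[(n - L):(n - 1)]))
  yp <- stats::filter(xp, h, method = "convolution", sides = 2)
  as.numeric(yp[(L + 1):(L + n)])
}
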