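## Digital filtering primitives used across the package.
##
## Everything here is deliberately dependency-free: IIR Butterworth design via
## the bilinear transform, zero-phase filtering with reflection padding,
## windowed-sinc FIR band-pass, FFT Hilbert transform, and Gaussian smoothing.

#' Butterworth filter coefficients
#'
#' Designs a digital Butterworth filter by the standard analog-prototype /
#' bilinear-transform route, matching the conventions of the classic signal
#' processing toolboxes (poles of the analog prototype on the unit
#' half-circle, cutoff prewarped, transfer function returned as `b`/`a`
#' polynomial coefficients in the z^-1 domain).
#'
#' @param n filter order (per band edge for `type = "band"`, i.e. the final
#'   band-pass has `2n` poles).
#' @param cutoff cutoff frequency in Hz (length 2 for `"band"`).
#' @param fs sampling rate in Hz.
#' @param type one of `"low"`, `"high"`, `"band"`.
#' @return list with numerator `b` and denominator `a` coefficient vectors.
#' @export
butter_design <- function(n, cutoff, fs, type = c("low", "high", "band")) {
  type <- match.arg(type)
  if (any(cutoff <= 0) || any(cutoff >= fs / 2))
    stop("cutoff must lie strictly inside (0, fs/2)")
  ## analog prototype poles (Butterworth, unit cutoff)
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  fs2 <- 2 * fs
  warp <- function(f) fs2 * tan(pi * f / fs)
  if (type == "low") {
    wc <- warp(cutoff)
    pa <- wc * p
    za <- complex(0)
    ka <- wc^n
  } else if (type == "high") {
    wc <- warp(cutoff)
    pa <- wc / p
    za <- rep(0 + 0i, n)
    ka <- 1
  } else {
    if (length(cutoff) != 2L) stop("band filter needs two cutoffs")
    w1 <- warp(cutoff[1]); w2 <- warp(cutoff[2])
    bw <- w2 - w1
    w0 <- sqrt(w1 * w2)
    ## lowpass prototype -> bandpass: each pole maps to a conjugate pair
    ps <- p * bw / 2
    pa <- c(ps + sqrt(ps^2 - w0^2), ps - sqrt(ps^2 - w0^2))
    za <- rep(0 + 0i, n)
    ka <- bw^n
  }
  ## bilinear transform s -> 2fs (z-1)/(z+1)
  pz <- (fs2 + pa) / (fs2 - pa)
  zz <- (fs2 + za) / (fs2 - za)
  ## zeros at analog infinity map to z = -1
  zz <- c(zz, rep(-1 + 0i, length(pa) - length(za)))
  kz <- Re(ka * prod(fs2 - za) / prod(fs2 - pa))
  b <- Re(poly_from_roots(zz)) * kz
  a <- Re(poly_from_roots(pz))
  list(b = b, a = a)
}

## polynomial coefficients (descending powers) from roots, via convolution
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

## single-pass IIR filter y = b/a * x with zero initial conditions,
## vectorised through stats::filter (FIR stage + recursive stage)
iir_filter <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b)
  u <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                     sides = 1)
  u <- as.numeric(u[nb:(nb - 1 + length(x))])
  if (length(a) > 1) {
    u <- as.numeric(stats::filter(u, -a[-1], method = "recursive"))
  }
  u
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Applies the filter forwards then backwards so the net phase response is
#' zero, with odd-reflection padding at both ends to suppress edge
#' transients.
#'
#' @param coefs list with `b`, `a` as returned by [butter_design()].
#' @param x numeric signal.
#' @return filtered signal, same length as `x`.
#' @export
filtfilt_zero_phase <- function(coefs, x) {
  b <- coefs$b; a <- coefs$a
  npad <- 3L * (max(length(a), length(b)) - 1L)
  if (length(x) <= npad + 1L) stop("signal too short for this filter order")
  head_pad <- 2 * x[1] - x[seq(npad + 1, 2)]
  tail_pad <- 2 * x[length(x)] - x[seq(length(x) - 1, length(x) - npad)]
  xe <- c(head_pad, x, tail_pad)
  y <- iir_filter(b, a, xe)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(npad + 1):(npad + length(x))]
}

#' Zero-phase band-pass convenience wrapper
#' @param x signal; @param band `c(lo, hi)` Hz; @param fs Hz;
#' @param order Butterworth order (default 3, the spindle-detector setting).
#' @export
bandpass_filter <- function(x, band, fs, order = 3) {
  filtfilt_zero_phase(butter_design(order, band, fs, "band"), x)
}

#' Windowed-sinc linear-phase FIR band-pass, applied with zero phase
#'
#' Order defaults to three cycles of the low cutoff (the EEG-toolbox
#' heuristic), forced even so the filter has an integer group delay that the
#' centred convolution cancels exactly.
#'
#' @inheritParams bandpass_filter
#' @param order FIR order; `NULL` for the 3-cycle heuristic.
#' @export
fir_bandpass <- function(x, band, fs, order = NULL) {
  if (band[2] >= fs / 2) stop("band must lie below Nyquist")
  if (is.null(order)) order <- 3L * floor(fs / band[1])
  if (order %% 2L == 1L) order <- order + 1L
  m <- order / 2
  k <- seq(-m, m)
  hi <- band[2] / (fs / 2); lo <- band[1] / (fs / 2)
  sinc <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))
  h <- hi * sinc(hi * k) - lo * sinc(lo * k)
  h <- h * (0.54 + 0.46 * cos(pi * k / m))   # Hamming
  ## normalise to unit gain at band centre
  f0 <- sqrt(band[1] * band[2])
  g <- abs(sum(h * exp(-2i * pi * f0 / fs * k)))
  h <- h / g
  npad <- length(h)
  xe <- c(2 * x[1] - x[seq(npad + 1, 2)], x,
          2 * x[length(x)] - x[seq(length(x) - 1, length(x) - npad)])
  y <- stats::filter(xe, h, method = "convolution", sides = 2)
  as.numeric(y[(npad + 1):(npad + length(x))])
}

#' Analytic signal via the FFT Hilbert transform
#' @param x real signal.
#' @return complex analytic signal; `Mod()` is the envelope, `Arg()` the
#'   instantaneous phase.
#' @export
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Gaussian smoothing by direct convolution (reflection-padded)
#' @param x signal; @param sd_samples kernel standard deviation in samples.
#' @export
gaussian_smooth <- function(x, sd_samples) {
  if (sd_samples <= 0) return(x)
  m <- ceiling(4 * sd_samples)
  k <- stats::dnorm(seq(-m, m), sd = sd_samples)
  k <- k / sum(k)
  npad <- length(k)
  xe <- c(x[seq(npad, 1)], x, x[seq(length(x), length(x) - npad + 1)])
  y <- stats::filter(xe, k, method = "convolution", sides = 2)
  as.numeric(y[(npad + 1):(npad + length(x))])
}
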