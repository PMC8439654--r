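## Multitaper spectral estimation (DPSS tapers, PSD, coherence).
##
## Defaults follow the toolbox convention used throughout the package:
## time-bandwidth product 3 with 5 tapers on 10 s windows, giving an
## effective bandwidth of +/- 0.3 Hz and a 0.1 Hz frequency grid.

.dpss_cache <- new.env(parent = emptyenv())

## Slepian sequences from the symmetric tridiagonal formulation
## (eigenvectors of the tridiagonal matrix commuting with the concentration
## operator). For long windows the tapers are computed on a 1024-point grid
## and spline-interpolated, then re-orthonormalised -- accurate to ~1e-5 for
## spectral work and orders of magnitude cheaper than the dense eigenproblem.
dpss_tapers <- function(n, nw = 3, k = 5) {
  key <- paste(n, nw, k, sep = "_")
  hit <- .dpss_cache[[key]]
  if (!is.null(hit)) return(hit)
  base_n <- 1024L
  if (n <= base_n) {
    tap <- dpss_dense(n, nw, k)
  } else {
    tap0 <- dpss_dense(base_n, nw, k)
    x0 <- seq(0, 1, length.out = base_n)
    x1 <- seq(0, 1, length.out = n)
    tap <- apply(tap0, 2, function(v) stats::spline(x0, v, xout = x1)$y)
    ## re-orthonormalise (Gram-Schmidt via QR keeps ordering and signs)
    qrd <- qr(tap)
    tap <- qr.Q(qrd) %*% sign(diag(diag(qr.R(qrd))))
  }
  ## polarity convention: symmetric tapers have positive mean,
  ## antisymmetric tapers start positive
  for (j in seq_len(ncol(tap))) {
    s <- sum(tap[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) tap[, j] <- -tap[, j]
    } else if (tap[which.max(abs(tap[, j]) > 1e-4), j] < 0) {
      tap[, j] <- -tap[, j]
    }
  }
  .dpss_cache[[key]] <- tap
  tap
}

dpss_dense <- function(n, nw, k) {
  w <- nw / n
  i <- seq_len(n) - 1
  d <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  e <- seq_len(n - 1) * (n - seq_len(n - 1)) / 2
  m <- diag(d)
  m[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- e
  m[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- e
  ev <- eigen(m, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  ## unit energy
  sweep(tap, 2, sqrt(colSums(tap^2)), "/")
}

## tapered FFTs of one window: matrix [n_freq x k]; the window is demeaned
## first so DC offsets cannot leak through taper sidelobes
taper_fft <- function(x, tapers, nfft) {
  x <- x - mean(x)
  n <- length(x)
  k <- ncol(tapers)
  out <- matrix(0 + 0i, nfft, k)
  for (j in seq_len(k)) {
    xt <- c(x * tapers[, j], rep(0, nfft - n))
    out[, j] <- stats::fft(xt)
  }
  out
}

#' Multitaper power spectral density per window
#'
#' Splits `x` into consecutive non-overlapping windows of `window_s` seconds
#' and returns one PSD row per window on a grid with spacing
#' `1 / window_s` Hz (10 s windows give the package's 0.1 Hz grid).
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds (default 10).
#' @param nw time-bandwidth product; @param k number of tapers.
#' @param starts_s optional explicit window start times (seconds); defaults
#'   to a full tiling of the signal.
#' @return list with `freq` (Hz), `psd` (matrix windows x freq) and
#'   `window_start_s`.
#' @export
mt_psd <- function(x, fs, window_s = 10, nw = 3, k = 5, starts_s = NULL) {
  n_win <- round(window_s * fs)
  if (is.null(starts_s)) {
    n_windows <- floor(length(x) / n_win)
    starts_s <- (seq_len(n_windows) - 1) * window_s
  }
  if (!length(starts_s)) stop("window extends past signal end")
  idx0 <- round(starts_s * fs)
  if (any(idx0 + n_win > length(x)))
    stop("window extends past signal end")
  tapers <- dpss_tapers(n_win, nw, k)
  nfft <- n_win
  nf <- floor(nfft / 2) + 1
  freq <- (seq_len(nf) - 1) * fs / nfft
  psd <- matrix(0, length(idx0), nf)
  for (w in seq_along(idx0)) {
    seg <- x[(idx0[w] + 1):(idx0[w] + n_win)]
    J <- taper_fft(seg, tapers, nfft)[seq_len(nf), , drop = FALSE]
    psd[w, ] <- rowMeans(Mod(J)^2) / fs
  }
  list(freq = freq, psd = psd, window_start_s = starts_s)
}

#' Multitaper coherence magnitude per window
#'
#' Coherence is estimated independently in each window from the `k` tapered
#' cross- and auto-spectra; the per-window magnitudes are in `[0, 1]`.
#'
#' @inheritParams mt_psd
#' @param y second signal, same length as `x`.
#' @param average how to combine windows into the summary `coherence`
#'   spectrum: `"magnitude"` (mean of per-window magnitudes, the default) or
#'   `"complex"` (magnitude of the mean complex coherency).
#' @return list with `freq`, `coh` (windows x freq magnitude matrix),
#'   `coherence` (summary spectrum) and `window_start_s`.
#' @export
mt_coherence <- function(x, y, fs, window_s = 10, nw = 3, k = 5,
                         starts_s = NULL,
                         average = c("magnitude", "complex")) {
  average <- match.arg(average)
  if (length(x) != length(y)) stop("signals must share length")
  n_win <- round(window_s * fs)
  if (is.null(starts_s)) {
    n_windows <- floor(length(x) / n_win)
    starts_s <- (seq_len(n_windows) - 1) * window_s
  }
  if (!length(starts_s)) stop("window extends past signal end")
  idx0 <- round(starts_s * fs)
  if (any(idx0 + n_win > length(x)))
    stop("window extends past signal end")
  tapers <- dpss_tapers(n_win, nw, k)
  nf <- floor(n_win / 2) + 1
  freq <- (seq_len(nf) - 1) * fs / n_win
  cohm <- matrix(0, length(idx0), nf)
  cplx <- matrix(0 + 0i, length(idx0), nf)
  for (w in seq_along(idx0)) {
    sl <- (idx0[w] + 1):(idx0[w] + n_win)
    Jx <- taper_fft(x[sl], tapers, n_win)[seq_len(nf), , drop = FALSE]
    Jy <- taper_fft(y[sl], tapers, n_win)[seq_len(nf), , drop = FALSE]
    sxy <- rowMeans(Jx * Conj(Jy))
    sxx <- rowMeans(Mod(Jx)^2)
    syy <- rowMeans(Mod(Jy)^2)
    cw <- sxy / sqrt(sxx * syy)
    cohm[w, ] <- Mod(cw)
    cplx[w, ] <- cw
  }
  summary_spec <- if (average == "magnitude") colMeans(cohm)
                  else Mod(colMeans(cplx))
  list(freq = freq, coh = cohm, coherence = summary_spec,
       window_start_s = starts_s)
}

#' Mean power in a frequency band
#'
#' Band edges are treated as closed intervals on the discrete grid.
#' @param freq frequency grid (Hz); @param spec spectrum (vector or matrix
#'   with frequency along columns); @param band `c(lo, hi)` in Hz.
#' @export
band_power <- function(freq, spec, band) {
  sel <- freq >= band[1] & freq <= band[2]
  if (!any(sel)) stop("band contains no frequency bins")
  if (is.matrix(spec)) rowMeans(spec[, sel, drop = FALSE])
  else mean(spec[sel])
}
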