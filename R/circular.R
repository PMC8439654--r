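## Circular statistics for spike-phase analyses.

#' Resultant vector length of a sample of angles
#' @param phases angles in radians.
#' @export
circ_resultant <- function(phases) {
  Mod(mean(exp(1i * phases)))
}

#' Circular mean angle
#' @param phases angles in radians.
#' @return mean direction in (-pi, pi].
#' @export
circ_mean <- function(phases) {
  Arg(mean(exp(1i * phases)))
}

#' Circular standard deviation
#'
#' Uses the circular (not angular) deviation `sqrt(-2 log Rbar)`, the
#' default of the classic directional-statistics toolboxes. Lower values
#' mean tighter phase concentration.
#'
#' @param phases angles in radians.
#' @export
circ_sd <- function(phases) {
  r <- circ_resultant(phases)
  if (r >= 1) return(0)
  sqrt(-2 * log(r))
}

#' Closed-form circular s.d. of a von Mises distribution
#'
#' For concentration `kappa` the population resultant is the Bessel ratio
#' `I1(kappa)/I0(kappa)`, hence cSD `= sqrt(-2 log(I1/I0))`. Used as an
#' independent oracle for the sample statistic.
#' @param kappa von Mises concentration parameter.
#' @export
vonmises_csd <- function(kappa) {
  r <- besselI(kappa, 1, expon.scaled = TRUE) /
       besselI(kappa, 0, expon.scaled = TRUE)
  sqrt(-2 * log(r))
}

#' Rayleigh test of circular uniformity
#'
#' `Z = n * Rbar^2` with the standard small-sample-corrected p
#' approximation.
#'
#' @param phases angles in radians; needs `n >= 5` to be testable.
#' @return list with `n`, `rbar`, `z` and `p` (`p = NA` when untestable).
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  if (n == 0) stop("no phases supplied")
  rbar <- circ_resultant(phases)
  if (n < 5) return(list(n = n, rbar = rbar, z = NA_real_, p = NA_real_,
                         testable = FALSE))
  z <- n * rbar^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * rbar)^2)) - (1 + 2 * n))
  list(n = n, rbar = rbar, z = z, p = min(max(p, .Machine$double.xmin), 1),
       testable = TRUE)
}

#' Draw von Mises random angles
#'
#' Best-Fisher rejection sampler; used by the synthetic generator and the
#' test oracles.
#' @param n sample size; @param mu mean direction; @param kappa
#'   concentration (`0` gives the uniform distribution).
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  out <- numeric(n)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    if (any(ok)) {
      th <- sign(u3[ok] - 0.5) * acos(f[ok])
      take <- min(sum(ok), n - got)
      out[(got + 1):(got + take)] <- th[seq_len(take)]
      got <- got + take
    }
  }
  wrap_angle(out + mu)
}

## wrap to (-pi, pi]
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}
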