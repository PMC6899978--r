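# Shinnar-Le Roux design of the PINS sub-pulse.
#
# The sub-pulse is specified as a linear-phase FIR prototype for the beta
# polynomial (weighted least squares), a minimum-phase alpha polynomial
# obtained by spectral factorization, and the exact inverse SLR hard-pulse
# recursion.  For a PINS train the hard-pulse flips are used directly: RF
# plays only while the gradient is zero, so the simulated profile equals
# the polynomial's frequency response evaluated at the per-blip precession
# angle.

# Parks-McClellan D-infinity estimate of the (transition width x length)
# product for ripples (d1, d2) (Herrmann et al. approximation).
d_inf <- function(d1, d2) {
  l1 <- log10(d1)
  l2 <- log10(d2)
  (0.005309 * l1^2 + 0.07114 * l1 - 0.4761) * l2 -
    (0.00266 * l1^2 + 0.5941 * l1 + 0.4278)
}

# Weighted least-squares linear-phase lowpass FIR of length n (type I or
# II).  fp/fs are band edges in cycles/sample; wp/ws the band weights.
ls_lowpass <- function(n, fp, fs, wp, ws, ngrid = 4096) {
  f <- seq(0, 0.5, length.out = ngrid)
  keep <- f <= fp | f >= fs
  f <- f[keep]
  D <- as.numeric(f <= fp)
  W <- ifelse(f <= fp, wp, ws)
  if (n %% 2L == 1L) {
    k <- 0:((n - 1L) %/% 2L)
    A <- cos(2 * pi * outer(f, k))
    A[, -1L] <- 2 * A[, -1L]
  } else {
    k <- seq_len(n %/% 2L)
    A <- 2 * cos(2 * pi * outer(f, k - 0.5))
  }
  c_hat <- qr.solve(A * W, D * W)
  h <- numeric(n)
  if (n %% 2L == 1L) {
    mid <- (n - 1L) %/% 2L + 1L
    h[mid] <- c_hat[1L]
    for (kk in seq_len((n - 1L) %/% 2L)) {
      h[mid + kk] <- c_hat[kk + 1L]
      h[mid - kk] <- c_hat[kk + 1L]
    }
  } else {
    half <- n %/% 2L
    for (kk in seq_len(half)) {
      h[half + kk] <- c_hat[kk]
      h[half - kk + 1L] <- c_hat[kk]
    }
  }
  h
}

# Minimum-phase polynomial (n coefficients) with prescribed magnitude on an
# FFT grid, via the real cepstrum.
mag2mp <- function(mag, n) {
  m <- length(mag)
  cep <- stats::fft(log(pmax(mag, 1e-16)), inverse = TRUE) / m
  fold <- complex(m)
  fold[1L] <- cep[1L]
  fold[2:(m %/% 2L)] <- 2 * cep[2:(m %/% 2L)]
  fold[m %/% 2L + 1L] <- cep[m %/% 2L + 1L]
  spec <- exp(stats::fft(fold))
  coef <- stats::fft(spec, inverse = TRUE) / m
  coef[seq_len(n)]
}

# Exact inverse SLR recursion: from polynomials (a, b) to hard-pulse
# rotations.  Returns complex flips phi * exp(1i * theta).
inverse_slr <- function(a, b) {
  n <- length(b)
  a <- as.complex(a)
  b <- as.complex(b)
  flips <- complex(n)
  for (j in n:1) {
    phi <- 2 * atan2(Mod(b[1L]), Mod(a[1L]))
    theta <- if (Mod(b[1L]) > 0) Arg(-1i * b[1L] / a[1L]) else 0
    flips[j] <- phi * exp(1i * theta)
    C <- cos(phi / 2)
    S <- 1i * exp(1i * theta) * sin(phi / 2)
    a_new <- C * a + Conj(S) * b
    b_new <- -S * a + C * b
    if (j > 1L) {
      a <- a_new[seq_len(j - 1L)]
      b <- b_new[2:j]
    }
  }
  flips
}

#' SLR sub-pulse design for crushed spin-echo refocusing
#'
#' Designs the beta-polynomial of an `n_samples`-tap refocusing sub-pulse
#' as a weighted least-squares linear-phase lowpass filter and recovers the
#' hard-pulse flip angles by the exact inverse SLR recursion.  The supplied
#' `d1` and `d2` are the passband and stopband ripples of the crushed-SE
#' profile `|b|^2`; the beta-polynomial ripples follow the standard
#' spin-echo conversion `(d1/4, sqrt(d2))`.  The fractional transition
#' width is the Parks-McClellan estimate `D_inf / TBWP`, capped at 0.9 so
#' that a nonzero flat passband survives ripple/TBWP combinations that are
#' otherwise infeasible (the cap binds for TBWP = 2 at the default
#' ripples).
#'
#' @param tbwp time-bandwidth product of the sub-pulse (>= 1).
#' @param d1 passband ripple of the refocusing profile (default `0.01/4`).
#' @param d2 stopband ripple of the refocusing profile (default `0.01/2`).
#' @param n_samples number of hard-pulse samples.
#' @param flip nominal on-resonance flip (rad); `pi` for refocusing.
#' @return An object of class `slr_design` with fields `flips` (signed
#'   hard-pulse rotations, rad), `b_poly`, `a_poly`, `d1b`, `d2b`
#'   (beta-polynomial ripples), `ftw` (fractional transition width) and the
#'   inputs.
#' @export
design_slr_subpulse <- function(tbwp, d1 = 0.01 / 4, d2 = 0.01 / 2,
                                n_samples, flip = pi) {
  stopifnot(tbwp >= 1, d1 > 0, d2 > 0, flip > 0, flip <= pi)
  if (n_samples < 4 * tbwp)
    stop("n_samples too small for the requested time-bandwidth product")
  d1b <- d1 / 4
  d2b <- sqrt(d2)
  ftw <- min(d_inf(d1b, d2b) / tbwp, 0.9)
  bw <- tbwp / n_samples
  fp <- (bw / 2) * (1 - ftw)
  fs <- (bw / 2) * (1 + ftw)
  if (fs > 0.5) stop("infeasible ripple/TBWP combination: stopband edge beyond Nyquist")
  h <- ls_lowpass(n_samples, fp, fs, 1 / d1b, 1 / d2b)
  nfft <- 2^ceiling(log2(max(64 * n_samples, 4096)))
  Bmag <- Mod(stats::fft(c(h, rep(0, nfft - n_samples))))
  # scale to the nominal flip and keep |B| <= 1 for the factorization
  h <- h * sin(flip / 2) / max(Bmag)
  Bmag <- Bmag * sin(flip / 2) / max(Bmag)
  a <- mag2mp(sqrt(pmax(0, 1 - Bmag^2)), n_samples)
  # a real (theta in {0, pi}) pulse has a purely imaginary beta polynomial
  # under this rotation convention; the global phase leaves |B| untouched
  fl <- inverse_slr(a, 1i * h)
  flips <- Re(fl * exp(-1i * Arg(fl))) * ifelse(cos(Arg(fl)) >= 0, 1, -1)
  structure(list(flips = flips, b_poly = h, a_poly = a,
                 tbwp = tbwp, d1 = d1, d2 = d2, d1b = d1b, d2b = d2b,
                 ftw = ftw, flip = flip, n_samples = n_samples),
            class = "slr_design")
}

#' @export
print.slr_design <- function(x, ...) {
  cat(sprintf("<slr_design> %d samples, TBWP %g, flip %.1f deg, sum(flips) = %.4f rad, peak |flip| = %.4f rad\n",
              x$n_samples, x$tbwp, x$flip * 180 / pi, sum(x$flips),
              max(abs(x$flips))))
  invisible(x)
}
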