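#' Spatial evaluation grid along the slice direction
#'
#' `nz` equidistant positions spanning `[-fov/2, fov/2]`, symmetric about
#' the isocenter, with resolution `delta = fov / nz`.
#'
#' @param fov_m field of view along slice select (m).
#' @param nz number of spatial points.
#' @return An object of class `spatial_grid` with fields `z`, `nz`,
#'   `delta`, `fov`.
#' @export
spatial_grid <- function(fov_m, nz) {
  stopifnot(fov_m > 0, nz >= 2)
  nz <- as.integer(nz)
  delta <- fov_m / nz
  z <- (seq_len(nz) - (nz + 1) / 2) * delta
  structure(list(z = z, nz = nz, delta = delta, fov = fov_m),
            class = "spatial_grid")
}

#' @export
print.spatial_grid <- function(x, ...) {
  cat(sprintf("<spatial_grid> %d points, FOV %.1f mm, delta %.3f mm\n",
              x$nz, x$fov * 1e3, x$delta * 1e3))
  invisible(x)
}

# sin(phi/2)/phi with a series fallback near phi = 0 (limit 1/2)
half_sinc <- function(phi) {
  out <- sin(phi / 2) / phi
  small <- abs(phi) < 1e-8
  if (any(small)) out[small] <- 0.5 - phi[small]^2 / 48
  out
}

# Per-step Cayley-Klein coefficients for all z at once.
# u = gamma * b1_scale * signed RF (rad/s), w = gamma*z*Gt + 2*pi*b0 (rad/s)
ck_coefficients <- function(u_re, u_im, w, tau) {
  rho <- sqrt(u_re^2 + u_im^2 + w^2)
  phi <- -tau * rho
  S <- half_sinc(phi)
  alpha <- complex(real = cos(phi / 2), imaginary = tau * w * S)
  beta <- 1i * tau * complex(real = u_re, imaginary = u_im) * S
  list(alpha = alpha, beta = beta)
}

#' Spin-domain Bloch simulation
#'
#' Propagates the Cayley-Klein pair `(a, b)` through the piecewise-constant
#' RF and (realized) gradient waveform for every position of a spatial
#' grid, starting from `a = 1, b = 0`.  Relaxation is neglected.  Per step
#' the rotation is
#' `alpha = cos(phi/2) + 1i*tau*w*sin(phi/2)/phi`,
#' `beta  = 1i*tau*gamma*B1*sin(phi/2)/phi`, with
#' `phi = -tau * sqrt((gamma*r*b1_scale)^2 + w^2)` and z-rotation rate
#' `w = gamma*z*Gt + 2*pi*b0_offset_Hz`.
#'
#' @param rf an [rf_waveform()] or complex vector of B1 samples (T).
#' @param grad_realized realized gradient samples (T/m), e.g. the output of
#'   [apply_girf()], or a [gradient_waveform()] (used unfiltered).
#' @param grid a [time_grid()].
#' @param space a [spatial_grid()].
#' @param b1_scale multiplicative RF scale (1 = nominal).
#' @param b0_offset_Hz constant off-resonance (Hz).
#' @param keep_history store the full state history (needed by the adjoint
#'   sweep; memory `nz x nt`).
#' @return An object of class `spin_profile` with complex vectors `a`, `b`
#'   per z (and matrices `a_hist`, `b_hist` when `keep_history = TRUE`).
#' @export
simulate_spin_domain <- function(rf, grad_realized, grid, space,
                                 b1_scale = 1, b0_offset_Hz = 0,
                                 keep_history = FALSE) {
  b1 <- if (inherits(rf, "rf_waveform")) rf_complex(rf) else as.complex(rf)
  g <- if (inherits(grad_realized, "gradient_waveform")) grad_realized$Gs
       else as.numeric(grad_realized)
  n <- n_intervals(grid)
  if (length(b1) != n || length(g) != n)
    stop("rf and gradient must have length nt - 1")
  if (any(!is.finite(Mod(b1))) || any(!is.finite(g)))
    stop("non-finite waveform samples")
  z <- space$z
  tau <- grid$tau
  a <- rep(1 + 0i, space$nz)
  b <- rep(0 + 0i, space$nz)
  if (keep_history) {
    a_hist <- matrix(0i, space$nz, n + 1L)
    b_hist <- matrix(0i, space$nz, n + 1L)
    a_hist[, 1L] <- a
    b_hist[, 1L] <- b
  }
  u <- GAMMA_1H * b1_scale * b1
  w0 <- 2 * pi * b0_offset_Hz
  for (m in seq_len(n)) {
    w <- GAMMA_1H * z * g[m] + w0
    ck <- ck_coefficients(Re(u[m]), Im(u[m]), w, tau)
    a_new <- ck$alpha * a - Conj(ck$beta) * b
    b_new <- ck$beta * a + Conj(ck$alpha) * b
    a <- a_new
    b <- b_new
    if (keep_history) {
      a_hist[, m + 1L] <- a
      b_hist[, m + 1L] <- b
    }
  }
  out <- list(a = a, b = b, z = z, space = space, grid = grid)
  if (keep_history) {
    out$a_hist <- a_hist
    out$b_hist <- b_hist
  }
  structure(out, class = "spin_profile")
}

#' @export
print.spin_profile <- function(x, ...) {
  cat(sprintf("<spin_profile> %d positions, max |b|^2 = %.4f, max |a|^2+|b|^2-1 = %.2e\n",
              length(x$b), max(Mod(x$b)^2), max(abs(Mod(x$a)^2 + Mod(x$b)^2 - 1))))
  invisible(x)
}

#' Compose two spin-domain propagators
#'
#' If `p1` and `p2` are the profiles of the first and second half of a
#' waveform (each started from `a = 1, b = 0`), the composition equals the
#' one-shot simulation of the whole waveform.
#'
#' @param p1,p2 objects of class `spin_profile` on the same spatial grid.
#' @export
compose_profiles <- function(p1, p2) {
  stopifnot(length(p1$b) == length(p2$b))
  a <- p2$a * p1$a - Conj(p2$b) * p1$b
  b <- p2$b * p1$a + Conj(p2$a) * p1$b
  structure(list(a = a, b = b, z = p1$z, space = p1$space, grid = p1$grid),
            class = "spin_profile")
}

#' Crushed spin-echo refocusing profile
#'
#' Magnitude `|b|^2` and phase `arg(b^2)` per position; the observable of a
#' perfectly crushed spin echo.
#'
#' @param p a `spin_profile`.
#' @return List with numeric vectors `magnitude` (in `[0, 1]`) and `phase`
#'   (rad, in `(-pi, pi]`).
#' @export
refocusing_profile <- function(p) {
  list(magnitude = Mod(p$b)^2, phase = Arg(p$b^2))
}

#' Excitation flip-angle profile
#'
#' `asin(|2 a b*|)` per position, the flip angle seen when a (scaled)
#' refocusing pulse is used for excitation.  The argument is clipped to
#' `[0, 1]` to guard against rounding overshoot.
#'
#' @param p a `spin_profile`.
#' @return Flip angle per z (rad).
#' @export
excitation_flip_angle <- function(p) {
  asin(pmin(pmax(Mod(2 * p$a * Conj(p$b)), 0), 1))
}

#' Grid of B1 scales and B0 offsets for robustness evaluation
#'
#' @param b1_scales multiplicative RF factors (dimensionless); the nominal
#'   1.0 is added if absent.
#' @param b0_offsets_Hz off-resonance values (Hz); 0 is added if absent.
#' @export
perturbation_grid <- function(b1_scales = seq(0.75, 1.25, by = 0.125),
                              b0_offsets_Hz = seq(-200, 200, by = 100)) {
  if (!any(abs(b1_scales - 1) < 1e-12)) b1_scales <- sort(c(b1_scales, 1))
  if (!any(b0_offsets_Hz == 0)) b0_offsets_Hz <- sort(c(b0_offsets_Hz, 0))
  stopifnot(all(is.finite(b1_scales)), all(is.finite(b0_offsets_Hz)))
  structure(list(b1_scales = b1_scales, b0_offsets_Hz = b0_offsets_Hz),
            class = "perturbation_grid")
}

#' B0/B1 robustness sweep
#'
#' Repeats [simulate_spin_domain()] over a [perturbation_grid()] and
#' collects refocusing magnitude and phase into arrays indexed by
#' `(b1_scale, b0_offset, z)`.
#'
#' @inheritParams simulate_spin_domain
#' @param perturb a [perturbation_grid()].
#' @return List of two 3-d arrays `magnitude` and `phase` with dimnames
#'   giving the perturbation values.
#' @export
robustness_sweep <- function(rf, grad_realized, grid, space, perturb) {
  stopifnot(inherits(perturb, "perturbation_grid"))
  nb1 <- length(perturb$b1_scales)
  nb0 <- length(perturb$b0_offsets_Hz)
  dn <- list(b1 = sprintf("%g", perturb$b1_scales),
             b0 = sprintf("%g", perturb$b0_offsets_Hz),
             z = NULL)
  mag <- array(NA_real_, c(nb1, nb0, space$nz), dimnames = dn)
  ph <- array(NA_real_, c(nb1, nb0, space$nz), dimnames = dn)
  for (i in seq_len(nb1)) {
    for (j in seq_len(nb0)) {
      p <- simulate_spin_domain(rf, grad_realized, grid, space,
                                b1_scale = perturb$b1_scales[i],
                                b0_offset_Hz = perturb$b0_offsets_Hz[j])
      prof <- refocusing_profile(p)
      mag[i, j, ] <- prof$magnitude
      ph[i, j, ] <- prof$phase
    }
  }
  list(magnitude = mag, phase = ph)
}

#' Export a refocusing profile as CSV
#'
#' Columns `z_mm`, `mag`, `phase_rad`.
#'
#' @param p a `spin_profile`.
#' @param file path to write.
#' @export
write_profile_csv <- function(p, file) {
  prof <- refocusing_profile(p)
  utils::write.csv(data.frame(z_mm = p$z * 1e3, mag = prof$magnitude,
                              phase_rad = prof$phase),
                   file, row.names = FALSE)
  invisible(file)
}
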