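# Independent brute-force oracles and shared fixtures.

# Rotation-matrix Bloch oracle: compose 3x3 Rodrigues rotations (the Bloch
# equation rotates magnetization by -gamma*|B_eff|*tau about B_eff) and
# read the crushed-SE observable off the net matrix: |b|^2 = (1 - Rzz) / 2.
oracle_refocusing <- function(b1, g, tau, z, b1_scale = 1, b0_hz = 0) {
  R <- diag(3)
  for (m in seq_along(b1)) {
    v <- c(GAMMA_1H * b1_scale * Re(b1[m]),
           GAMMA_1H * b1_scale * Im(b1[m]),
           GAMMA_1H * z * g[m] + 2 * pi * b0_hz)
    nv <- sqrt(sum(v^2))
    if (nv > 0) {
      ang <- -tau * nv
      nh <- v / nv
      K <- matrix(c(0, -nh[3], nh[2],
                    nh[3], 0, -nh[1],
                    -nh[2], nh[1], 0), 3, 3, byrow = TRUE)
      R <- (diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)) %*% R
    }
  }
  (1 - R[3, 3]) / 2
}

# random test waveform on n intervals (complex RF unless real = TRUE)
random_waveform <- function(n, real = FALSE, rf_scale = 5e-6,
                            g_scale = 10e-3) {
  b1 <- if (real) complex(real = stats::rnorm(n) * rf_scale)
        else complex(real = stats::rnorm(n) * rf_scale,
                     imaginary = stats::rnorm(n) * rf_scale)
  list(b1 = b1, g = stats::rnorm(n) * g_scale)
}

# small two-slice problem used by gradient and solver tests
tiny_problem <- function(girf = NULL, nz = 63, phase_constrained = TRUE) {
  space <- spatial_grid(0.06, nz)
  spec <- build_slice_domains(2, 6e-3, 60e-3, 2, space, ftw = 0.4)
  design_problem(spec, hardware_bounds(),
                 profile_bounds(0.02, 0.025), girf = girf,
                 phase_constrained = phase_constrained)
}

random_controls <- function(n, grid, seed = 7) {
  withr::with_seed(seed, {
    u <- stats::rnorm(n) * 4e-6
    s <- stats::rnorm(n) * 50
    control_vector(abs(u), ifelse(u >= 0, 0, pi), s, grid)
  })
}

# central finite-difference gradient of the cost for the signed-real
# parameterization (u, s)
fd_gradient <- function(u, s, grid, problem, pen, h_rel = 1e-6) {
  J <- function(uv, sv) {
    x <- control_vector(abs(uv), ifelse(uv >= 0, 0, pi), sv, grid)
    design_cost(x, problem, pen)$J
  }
  n <- length(u)
  hu <- h_rel * max(abs(u))
  hs <- h_rel * max(abs(s))
  fd_u <- fd_s <- numeric(n)
  for (i in seq_len(n)) {
    up <- u; um <- u; up[i] <- up[i] + hu; um[i] <- um[i] - hu
    fd_u[i] <- (J(up, s) - J(um, s)) / (2 * hu)
    s1 <- s; s2 <- s; s1[i] <- s1[i] + hs; s2[i] <- s2[i] - hs
    fd_s[i] <- (J(u, s1) - J(u, s2)) / (2 * hs)
  }
  c(fd_u, fd_s)
}

rel_err <- function(a, b) sqrt(sum((a - b)^2)) / max(sqrt(sum(b^2)), 1e-300)
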