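# Exact first derivatives of the penalized cost by an adjoint sweep over
# the Cayley-Klein recursion, chained through the GIRF filter (transpose =
# filtering with Conj(H)) and the slew integration map (transpose =
# reversed cumulative sum times tau).

# d/dphi of sin(phi/2)/phi, with series fallback near 0
d_half_sinc <- function(phi) {
  out <- numeric(length(phi))
  small <- abs(phi) < 1e-6
  out[small] <- -phi[small] / 24
  ph <- phi[!small]
  out[!small] <- cos(ph / 2) / (2 * ph) - sin(ph / 2) / ph^2
  out
}

#' Gradient of the design cost by the adjoint method
#'
#' Runs the forward spin-domain simulation storing the state history, forms
#' the terminal Wirtinger derivative of all profile-dependent penalty terms
#' with respect to `b`, sweeps the adjoint pair backwards through the
#' recursion accumulating the sensitivities to the per-interval RF
#' (real/imaginary parts) and realized gradient, and maps the realized
#' gradient sensitivity back to the slew controls through the transposed
#' GIRF operator and slew integration.  Direct terms (RF energy, demanded
#' gradient penalty) are added analytically.
#'
#' @param x a [control_vector()].
#' @param problem a [design_problem()].
#' @param pen a [penalty_state()].
#' @return List with the cost value `J`, `terms`, and gradient components
#'   `d_r`, `d_theta`, `d_s` (and `d_b1_re`, `d_b1_im` for the signed-real
#'   parameterization).
#' @export
cost_gradient <- function(x, problem, pen) {
  stopifnot(inherits(x, "control_vector"), inherits(problem, "design_problem"),
            inherits(pen, "penalty_state"))
  grid <- x$grid
  n <- n_intervals(grid)
  tau <- grid$tau
  space <- problem$space
  spec <- problem$spec
  pb <- problem$pbounds
  p <- pen$p
  delta <- space$delta
  z <- space$z
  st <- forward_state(x, problem, pen, keep_history = TRUE)
  ct <- cost_terms(st, x, problem, pen)
  prof <- st$profile
  bN <- prof$b
  mag <- st$magnitude

  # terminal Wirtinger derivative dJ/db (a-independent profile terms)
  vb <- complex(space$nz)
  e_out <- rep_len(pb$e_out, space$nz)
  e_in <- rep_len(pb$e_in, space$nz)
  out <- spec$out_slice
  ins <- spec$in_slice
  vb[out] <- delta * pen$mu_out / 2 *
    (mag[out] / e_out[out])^(p - 1) * Conj(bN[out]) / e_out[out]
  vb[ins] <- vb[ins] - delta * pen$mu_in / 2 *
    ((1 - mag[ins]) / e_in[ins])^(p - 1) * Conj(bN[ins]) / e_in[ins]
  # phase term: dJ/dphase with the mean-phasor dependence, then to b
  if (problem$phase_constrained) {
    dev <- ct$phase_stats$dev
    gph <- numeric(space$nz)
    gph[ins] <- delta * pen$mu_p / pb$ep * (dev[ins] / pb$ep)^(p - 1)
    for (l in seq_len(spec$mb)) {
      idx <- which(spec$slice_index == l)
      ph <- st$phase[idx]
      P <- sum(exp(1i * ph))
      cz <- Re(exp(1i * ph) * Conj(P)) / Mod(P)^2
      gph[idx] <- gph[idx] - cz * sum(gph[idx])
    }
    safe <- Mod(bN) > 1e-8
    vb[safe] <- vb[safe] + gph[safe] * (-1i / bN[safe])
  }
  va <- complex(space$nz)

  # backward sweep
  u <- GAMMA_1H * st$b1                   # rad/s complex nutation rate
  g_ure <- numeric(n)
  g_uim <- numeric(n)
  g_Gt <- numeric(n)
  gz <- GAMMA_1H * z
  for (m in n:1) {
    a_prev <- prof$a_hist[, m]
    b_prev <- prof$b_hist[, m]
    w <- gz * st$Gt[m]
    ure <- Re(u[m]); uim <- Im(u[m])
    rho <- sqrt(ure^2 + uim^2 + w^2)
    phi <- -tau * rho
    S <- half_sinc(phi)
    dS <- d_half_sinc(phi)
    cphi <- cos(phi / 2)
    alpha <- complex(real = cphi, imaginary = tau * w * S)
    beta <- 1i * tau * complex(real = ure, imaginary = uim) * S
    rho_safe <- pmax(rho, 1e-30)
    dphi_dure <- -tau * ure / rho_safe
    dphi_duim <- -tau * uim / rho_safe
    dphi_dw <- -tau * w / rho_safe
    dalpha_dphi <- complex(real = -sin(phi / 2) / 2, imaginary = tau * w * dS)
    b1c <- complex(real = ure, imaginary = uim)
    # sensitivity contraction: dJ/dc = 2 Re sum_z [va * da + vb * db]
    # with da = dalpha a - Conj(dbeta) b, db = dbeta a + Conj(dalpha) b;
    # the four state products are shared by all three control directions
    A1 <- va * a_prev
    A2 <- vb * b_prev
    B1 <- vb * a_prev
    B2 <- va * b_prev
    contract <- function(dalpha, dbeta) {
      sum(Re(dalpha * A1) + Re(Conj(dalpha) * A2) +
            Re(dbeta * B1) - Re(Conj(dbeta) * B2))
    }
    dal_ure <- dalpha_dphi * dphi_dure
    dbe_ure <- 1i * tau * (S + b1c * dS * dphi_dure)
    g_ure[m] <- 2 * contract(dal_ure, dbe_ure)
    if (!x$real_valued) {
      dal_uim <- dalpha_dphi * dphi_duim
      dbe_uim <- 1i * tau * (1i * S + b1c * dS * dphi_duim)
      g_uim[m] <- 2 * contract(dal_uim, dbe_uim)
    }
    dal_w <- dalpha_dphi * dphi_dw + 1i * tau * S
    dbe_w <- 1i * tau * b1c * dS * dphi_dw
    g_Gt[m] <- 2 * sum(gz * (Re(dal_w * A1) + Re(Conj(dal_w) * A2) +
                               Re(dbe_w * B1) - Re(Conj(dbe_w) * B2)))
    # pull the adjoint back one step: v_{m-1} = v_m Q_m
    va_new <- va * alpha + vb * beta
    vb_new <- -va * Conj(beta) + vb * Conj(alpha)
    va <- va_new
    vb <- vb_new
  }

  # chain to controls
  d_Gs <- if (is.null(problem$girf)) g_Gt else st$flt$adjoint(g_Gt)
  d_Gs <- d_Gs + tau * pen$mu_g / problem$bounds$gmax *
    (st$Gs / problem$bounds$gmax)^(p - 1)
  d_s <- tau * rev(cumsum(rev(d_Gs)))
  # RF: u = gamma * b1; plus the direct energy term (r in uT inside the cost)
  d_b1_re <- GAMMA_1H * g_ure
  d_b1_im <- GAMMA_1H * g_uim
  ct_r <- cos(x$theta); st_r <- sin(x$theta)
  d_r <- d_b1_re * ct_r + d_b1_im * st_r + tau * pen$mu_rf * (x$r * 1e12)
  d_theta <- x$r * (-d_b1_re * st_r + d_b1_im * ct_r)
  list(J = ct$J, terms = ct$terms,
       d_r = d_r, d_theta = d_theta, d_s = d_s,
       d_b1_re = d_b1_re + tau * pen$mu_rf * 1e12 * Re(st$b1),
       d_b1_im = d_b1_im + tau * pen$mu_rf * 1e12 * Im(st$b1))
}
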