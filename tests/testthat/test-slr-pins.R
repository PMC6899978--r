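# Simulate an idealized PINS train (one-sample hard pulses, one-sample
# blips) so the profile equals the SLR polynomial response exactly.
simulate_subpulse_profile <- function(slr, spacing = 30e-3, nz = 2001) {
  tau <- 6.4e-6
  n <- slr$n_samples
  nt <- 2L * n - 1L
  b1 <- complex(real = rep(0, nt))
  g <- rep(0, nt)
  b1[seq(1, nt, by = 2)] <- slr$flips / (GAMMA_1H * tau)
  g[seq(2, nt, by = 2)] <- 2 * pi / (GAMMA_1H * spacing) / tau
  p <- simulate_spin_domain(b1, g, time_grid(tau, nt + 1L),
                            spatial_grid(spacing, nz))
  list(z = p$z, mag = refocusing_profile(p)$magnitude,
       thk = slr$tbwp * spacing / n)
}

test_that("SLR sub-pulse meets its profile ripples when feasible", {
  for (co in list(c(3, 18), c(4, 48))) {
    slr <- design_slr_subpulse(co[1], n_samples = co[2])
    pr <- simulate_subpulse_profile(slr)
    edge_in <- (pr$thk / 2) * (1 - slr$ftw)
    edge_out <- (pr$thk / 2) * (1 + slr$ftw)
    ctr <- which.min(abs(pr$z))
    # in-slice: 1 - |b|^2 <= d1 (passband ripple of the crushed-SE profile)
    expect_gte(pr$mag[ctr], 1 - slr$d1)
    expect_lte(max(1 - pr$mag[abs(pr$z) <= edge_in]), slr$d1 * 1.25)
    # far out-of-slice: |b|^2 <= d2
    expect_lte(max(pr$mag[abs(pr$z) >= 1.5 * edge_out]), slr$d2)
    # whole stopband stays below the 1% profile error of the initial pulse
    expect_lte(max(pr$mag[abs(pr$z) >= edge_out]), 0.01)
    # flips are a real pi rotation on resonance
    expect_equal(sum(slr$flips), pi, tolerance = 0.08)
  }
})

test_that("measured transition width tracks the D-infinity estimate", {
  for (co in list(c(3, 18), c(4, 48), c(2, 40))) {
    slr <- design_slr_subpulse(co[1], n_samples = co[2])
    pr <- simulate_subpulse_profile(slr, nz = 4001)
    right <- pr$z > 0
    zr <- pr$z[right]
    mr <- pr$mag[right]
    z_hi <- zr[max(which(mr >= 0.99))]
    z_lo <- zr[min(which(mr <= 0.01 & zr > z_hi))]
    expect_equal((z_lo - z_hi) / (pr$thk * slr$ftw), 1, tolerance = 0.2)
  }
})

test_that("design rejects impossible requests", {
  expect_error(design_slr_subpulse(4, n_samples = 8), "n_samples")
  expect_error(design_slr_subpulse(0.5, n_samples = 32))
})

test_that("slice domains partition the grid and scale with ftw", {
  sp <- spatial_grid(120e-3, 480)
  spec <- build_slice_domains(4, 2e-3, 120e-3, 4, sp)
  expect_equal(sum(spec$in_slice) + sum(spec$transition) +
                 sum(spec$out_slice), sp$nz)
  expect_false(any(spec$in_slice & spec$out_slice))
  expect_equal(spec$centers, c(-45, -15, 15, 45) * 1e-3)
  # single centered slice is symmetric about 0
  sp1 <- spatial_grid(30e-3, 121)
  s1 <- build_slice_domains(1, 5e-3, 30e-3, 3, sp1)
  expect_equal(s1$in_slice, rev(s1$in_slice))
  # shrinking the transition to zero makes in/out cover the grid
  s0 <- build_slice_domains(4, 2e-3, 120e-3, 4, sp, ftw = 0)
  expect_equal(sum(s0$transition), 0)
  expect_equal(sum(s0$in_slice) + sum(s0$out_slice), sp$nz)
  # overlapping slices (thick slices, wide transitions) are rejected
  expect_error(build_slice_domains(8, 14e-3, 120e-3, 2, sp), "overlap")
  expect_error(build_slice_domains(4, 40e-3, 120e-3, 4, sp), "fit")
})

test_that("PINS is feasible, deterministic and monotone in the bounds", {
  hb <- hardware_bounds()
  p <- build_pins(3, 2, 2e-3, 120e-3, hb, 6.4e-6)
  # already feasible: projection changes nothing
  x <- pins_controls(p)
  px <- project_controls(x, hb)
  expect_identical(px$r, x$r)
  expect_identical(px$s, x$s)
  expect_lte(max(p$rf$r), hb$rmax)
  expect_lte(max(abs(p$grad$Gs)), hb$gmax)
  expect_lte(max(abs(p$grad$s)), hb$smax + 1e-9)
  # deterministic
  p2 <- build_pins(3, 2, 2e-3, 120e-3, hb, 6.4e-6)
  expect_identical(p2$duration_ms, p$duration_ms)
  expect_identical(rf_signed(p2$rf), rf_signed(p$rf))
  # doubling rmax shortens the pulse (RF-on time roughly halves)
  p_hi <- build_pins(3, 2, 2e-3, 120e-3, hardware_bounds(26, 30, 180),
                     6.4e-6)
  expect_lt(p_hi$duration_ms, p$duration_ms)
  rf_on <- p$n_subpulses * p$n_sub_samples
  rf_on_hi <- p_hi$n_subpulses * p_hi$n_sub_samples
  expect_equal(rf_on_hi / rf_on, 0.5, tolerance = 0.15)
})

test_that("simulated PINS profile meets the 1% error bound on all slices", {
  hb <- hardware_bounds()
  for (cs in list(c(5, 4, 2), c(3, 2, 2))) {
    p <- build_pins(cs[1], cs[2], cs[3] * 1e-3, 120e-3, hb, 6.4e-6)
    sp <- spatial_grid(120e-3, 1200)
    spec <- build_slice_domains(cs[1], cs[3] * 1e-3, 120e-3, cs[2], sp)
    problem <- design_problem(spec, hb, profile_bounds(0.01, 0.025))
    m <- evaluate_design(p$rf, p$grad, problem, NULL)
    expect_lte(m$max_es, 0.01)
    vm <- magnitude_violations(m$magnitude, spec, problem$pbounds)
    expect_lte(max(vm), 0)
  }
})
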