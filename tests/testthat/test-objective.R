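test_that("magnitude violations are signed distances to the bounds", {
  sp <- spatial_grid(0.06, 63)
  spec <- build_slice_domains(2, 6e-3, 60e-3, 2, sp, ftw = 0.4)
  pb <- profile_bounds(0.02, 0.025)
  # perfect profile: no violations on the constrained domains
  perfect <- ifelse(spec$in_slice, 1, 0)
  vperf <- magnitude_violations(perfect, spec, pb)
  expect_lte(max(vperf[spec$in_slice | spec$out_slice]), -0.02 + 1e-12)
  # a single out-of-slice leak of 0.05 against e_out = 0.02 violates by 0.03
  leak <- perfect
  i_out <- which(spec$out_slice)[1]
  leak[i_out] <- 0.05
  v <- magnitude_violations(leak, spec, pb)
  expect_equal(v[i_out], 0.03)
  # transition points contribute exactly zero
  expect_true(all(v[spec$transition] == 0))
})

test_that("phase violations use a wrap-safe slice mean", {
  sp <- spatial_grid(0.06, 63)
  spec <- build_slice_domains(2, 6e-3, 60e-3, 2, sp, ftw = 0.4)
  pb <- profile_bounds(0.02, 0.025)
  # constant phase: violation is exactly -e_p on every in-slice point
  ph <- rep(0.3, sp$nz)
  v <- phase_violations(ph, spec, pb)
  expect_true(all(abs(v[spec$in_slice] + pb$ep) < 1e-12))
  # +-0.05 rad spread vs e_p = 0.025: worst violation +0.025
  idx <- which(spec$slice_index == 1)
  ph2 <- rep(0, sp$nz)
  ph2[idx] <- rep(c(0.05, -0.05), length.out = length(idx))
  v2 <- phase_violations(ph2, spec, pb)
  expect_equal(max(v2[idx]), 0.025, tolerance = 1e-10)
  # phases straddling the +-pi branch behave like the unwrapped case
  ph3 <- ph2
  ph3[idx] <- pi + ph2[idx]   # wraps to around -pi/+pi
  ph3 <- wrap <- atan2(sin(ph3), cos(ph3))
  v3 <- phase_violations(ph3, spec, pb)
  expect_equal(v3[idx], v2[idx], tolerance = 1e-10)
})

test_that("SAR estimate follows the closed form and ignores RF phase", {
  grid <- time_grid(6.4e-6, 2)
  cfg <- sar_config(16.67, 0.25, 3.2)
  rf0 <- rf_waveform(0, 0, grid)
  expect_equal(sar_estimate(rf0, grid, cfg), 0)
  rf1 <- rf_waveform(1e-6, 0, grid)  # 1 uT for one raster interval
  expect_equal(sar_estimate(rf1, grid, cfg), 0.25 * 16.67 * 6.4e-6)
  # phase invariance
  grid2 <- time_grid(6.4e-6, 33)
  set.seed(11)
  amp <- abs(rnorm(32)) * 1e-5
  a <- rf_waveform(amp, 0, grid2)
  b <- rf_waveform(amp, runif(32, -pi, pi), grid2, real_valued = FALSE)
  expect_equal(sar_estimate(a, grid2, cfg), sar_estimate(b, grid2, cfg))
})

test_that("cost reduces to the duration when penalties vanish", {
  problem <- tiny_problem()
  grid <- time_grid(6.4e-6, 41)
  x <- random_controls(40, grid)
  tiny <- penalty_state(mu_rf = 1e-300, mu_g = 1e-300, mu_out = 1e-300,
                        mu_in = 1e-300, mu_p = 1e-300, p = 2)
  expect_error(penalty_state(p = 3), "even")
  expect_error(penalty_state(mu_rf = 0), "positive")
  co <- design_cost(x, problem, tiny)
  expect_equal(co$J, grid$T, tolerance = 1e-12)
  # zero controls: profile b = 0 -> only the in-slice term is active
  x0 <- control_vector(rep(0, 40), rep(0, 40), rep(0, 40), grid)
  pen <- penalty_state()
  co0 <- design_cost(x0, problem, pen)
  expect_gt(co0$terms[["in_slice"]], 0)
  expect_equal(co0$terms[["rf"]], 0)
  expect_equal(co0$terms[["grad"]], 0)
  expect_equal(co0$terms[["out"]], 0)
  expect_gte(co0$J, grid$T)   # J >= T always
})

test_that("weight adaptation doubles on violation and relaxes with margin", {
  problem <- tiny_problem()
  grid <- time_grid(6.4e-6, 41)
  pen <- penalty_state()
  # zero RF: in-slice violated, out-of-slice satisfied with full margin
  x0 <- control_vector(rep(0, 40), rep(0, 40), rep(0, 40), grid)
  co <- design_cost(x0, problem, pen)
  pen2 <- adapt_weights(pen, co, problem)
  expect_equal(pen2$mu_in, 2 * pen$mu_in)
  expect_equal(pen2$mu_out, pen$mu_out / 1.25)
  expect_equal(pen2$mu_g, pen$mu_g / 1.25)
  # repeated adaptation under persistent violation grows geometrically to
  # the clamp
  p_it <- pen
  for (k in 1:40) p_it <- adapt_weights(p_it, co, problem)
  expect_equal(p_it$mu_in, 1e9)
  expect_gte(p_it$mu_out, 1e-6)
  # SAR above the limit doubles the RF energy weight
  co_hot <- co
  co_hot$sar <- 5
  pen3 <- adapt_weights(pen, co_hot, problem)
  expect_equal(pen3$mu_rf, 2 * pen$mu_rf)
})

test_that("p continuation doubles and saturates; Lp approaches the max", {
  pen <- penalty_state(p = 2)
  pen <- continue_p(pen)
  expect_equal(pen$p, 4L)
  for (k in 1:6) pen <- continue_p(pen)
  expect_equal(pen$p, 32L)
  # normalized Lp penalty sums approach the max violation as p grows
  v <- c(0.2, 0.5, 0.9, 1.1)
  lp <- sapply(c(2, 4, 8, 16, 32), function(p) sum(v^p)^(1 / p))
  expect_true(all(diff(lp) < 0))
  expect_equal(lp[5], max(v), tolerance = 0.1)
})

test_that("evaluation metrics match the objective's internal violations", {
  hb <- hardware_bounds()
  pins <- build_pins(2, 3, 6e-3, 60e-3, hb, 6.4e-6)
  sp <- spatial_grid(0.06, 255)
  spec <- build_slice_domains(2, 6e-3, 60e-3, 3, sp)
  problem <- design_problem(spec, hb, profile_bounds(0.02, 0.025))
  m <- evaluate_design(pins$rf, pins$grad, problem, NULL)
  co <- design_cost(pins_controls(pins), problem, penalty_state())
  expect_equal(m$magnitude, co$magnitude, tolerance = 1e-12)
  expect_equal(m$max_violation, co$max_violation, tolerance = 1e-12)
  expect_equal(m$sar_w_per_kg, sar_estimate(pins$rf), tolerance = 1e-12)
  expect_equal(m$T_ms, pins$duration_ms)
})
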