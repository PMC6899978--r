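test_that("slew integration and differencing are exact inverses", {
  grid <- time_grid(6.4e-6, 101)
  expect_equal(integrate_slew(rep(0, 100), grid)$Gs, rep(0, 100))
  g2 <- integrate_slew(c(180, -180, rep(0, 98)), grid)
  expect_equal(g2$Gs[1:3], c(6.4e-6 * 180, 0, 0))
  set.seed(1)
  s <- rnorm(100) * 100
  gw <- integrate_slew(s, grid)
  expect_equal(diff(c(0, gw$Gs)) / grid$tau, s, tolerance = 1e-12)
  expect_equal(gw$s, s, tolerance = 1e-12)
})

test_that("control projection clamps, is idempotent and non-expansive", {
  grid <- time_grid(6.4e-6, 11)
  hb <- hardware_bounds(13, 30, 180)
  x <- control_vector(c(15e-6, rep(5e-6, 9)), rep(0, 10),
                      c(250, rep(-10, 9)), grid)
  px <- project_controls(x, hb)
  expect_equal(px$r[1], 13e-6)
  expect_equal(px$s[1], 180)
  expect_equal(px$r[-1], x$r[-1])
  # idempotence and identity on the feasible set
  expect_identical(project_controls(px, hb)[c("r", "theta", "s")],
                   px[c("r", "theta", "s")])
  set.seed(2)
  for (k in 1:20) {
    a <- control_vector(abs(rnorm(10)) * 2e-5, runif(10, -4, 4),
                        rnorm(10) * 300, grid, real_valued = FALSE)
    b <- control_vector(abs(rnorm(10)) * 2e-5, runif(10, -4, 4),
                        rnorm(10) * 300, grid, real_valued = FALSE)
    pa <- project_controls(a, hb)
    pb <- project_controls(b, hb)
    da <- c(a$r - b$r, a$theta - b$theta, a$s - b$s)
    dp <- c(pa$r - pb$r, pa$theta - pb$theta, pa$s - pb$s)
    expect_lte(sqrt(sum(dp^2)), sqrt(sum(da^2)) + 1e-14)
  }
})

test_that("resampling preserves constants and ramp endpoints", {
  hb <- hardware_bounds()
  grid <- time_grid(6.4e-6, 41)
  x <- control_vector(rep(5e-6, 40), rep(0, 40), rep(10, 40), grid)
  same <- resample_controls(x, grid, hb)
  expect_equal(same$r, x$r)
  half <- resample_controls(x, time_grid(6.4e-6, 21), hb)
  expect_equal(half$r, rep(5e-6, 20))
  # linear ramp in RF: midpoint interpolation keeps the interior linear
  ramp <- control_vector(seq(1e-6, 8e-6, length.out = 40), rep(0, 40),
                         rep(0, 40), grid)
  down <- resample_controls(ramp, time_grid(6.4e-6, 21), hb)
  expect_equal(diff(down$r), rep(diff(down$r)[1], 19), tolerance = 1e-9)
  expect_equal(mean(down$r), mean(ramp$r), tolerance = 1e-9)
  expect_error(resample_controls(x, time_grid(3.2e-6, 21), hb), "tau")
})

test_that("waveform CSV round trip is exact", {
  grid <- time_grid(6.4e-6, 33)
  set.seed(3)
  u <- rnorm(32) * 1e-5
  rf <- rf_waveform(abs(u), ifelse(u >= 0, 0, pi), grid)
  gw <- integrate_slew(rnorm(32) * 50, grid)
  f <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(rf, gw, f)
  back <- read_waveform_csv(f)
  expect_identical(back$grid$nt, grid$nt)
  expect_identical(back$grid$tau, grid$tau)
  expect_identical(rf_signed(back$rf), rf_signed(rf))
  expect_identical(back$grad$Gs, gw$Gs)
  # file-level round trip: re-writing the parsed waveforms is bit-identical
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(back$rf, back$grad, f2)
  expect_identical(readLines(f2), readLines(f))
  # complex mode
  rfc <- rf_waveform(abs(u), runif(32, -pi, pi), grid, real_valued = FALSE)
  write_waveform_csv(rfc, gw, f)
  backc <- read_waveform_csv(f)
  expect_equal(rf_complex(backc$rf), rf_complex(rfc), tolerance = 1e-14)
})

test_that("waveform constructors validate their invariants", {
  grid <- time_grid(6.4e-6, 11)
  expect_error(time_grid(-1, 10))
  expect_error(time_grid(6.4e-6, 1), "nt")
  expect_error(rf_waveform(rep(-1e-6, 10), 0, grid), "non-negative")
  expect_error(rf_waveform(rep(1e-6, 10), pi / 3, grid), "real_valued")
  expect_error(gradient_waveform(rep(NA_real_, 10), grid), "finite")
  expect_error(integrate_slew(rep(0, 5), grid), "length")
  expect_equal(time_grid(6.4e-6, 101)$T, 100 * 6.4e-6)
})
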