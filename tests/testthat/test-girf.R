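test_that("identity response returns the input to machine precision", {
  grid <- time_grid(6.4e-6, 201)
  set.seed(4)
  g <- rnorm(200) * 5e-3
  out <- apply_girf(gradient_waveform(g, grid), ideal_girf())
  expect_lt(max(abs(out - g)), 1e-12)
  expect_equal(apply_girf(rep(0, 200), ideal_girf(), grid), rep(0, 200))
})

test_that("frequency-domain filtering equals time-domain convolution", {
  grid <- time_grid(6.4e-6, 129)
  n <- 128
  set.seed(5)
  g <- rnorm(n) * 5e-3
  tf <- synthetic_girf(3750, delay_s = 50e-6, order = 2)
  y <- apply_girf(g, tf, grid)
  # oracle: explicit zero-padded convolution with the impulse response
  npad <- 2^ceiling(log2(2 * n))
  freqs <- c(seq(0, npad / 2), seq(-npad / 2 + 1, -1)) / (npad * grid$tau)
  h <- Re(stats::fft(girfpulse:::girf_on_fft_grid(tf, freqs),
                     inverse = TRUE) / npad)
  gp <- c(g, rep(0, npad - n))
  y_conv <- sapply(seq_len(n), function(m) {
    k <- ((m - seq_len(npad)) %% npad) + 1
    sum(h * gp[k])
  })
  expect_lt(max(abs(y - y_conv)), 1e-8)
})

test_that("filtering is linear and consistent with the dense operator", {
  grid <- time_grid(6.4e-6, 41)
  tf <- synthetic_girf(5000, delay_s = 20e-6)
  set.seed(6)
  x1 <- rnorm(40); x2 <- rnorm(40)
  lin <- apply_girf(2 * x1 - 3 * x2, tf, grid)
  sep <- 2 * apply_girf(x1, tf, grid) - 3 * apply_girf(x2, tf, grid)
  expect_lt(max(abs(lin - sep)), 1e-10)
  op <- girf_filter_matrix(tf, grid)
  expect_lt(max(abs(op$A %*% x1 - apply_girf(x1, tf, grid))), 1e-10)
  # identity H gives the identity matrix
  opi <- girf_filter_matrix(ideal_girf(), grid)
  expect_lt(max(abs(opi$A - diag(40))), 1e-10)
  # adjoint identity <A x, y> = <x, A' y>, both dense and FFT paths
  y <- rnorm(40)
  expect_lt(abs(sum((op$A %*% x1) * y) - sum(x1 * (op$At %*% y))), 1e-12)
  expect_lt(max(abs(op$adjoint(y) - op$At %*% y)), 1e-12)
})

test_that("a pure tone is scaled by |H| and delayed by the group delay", {
  tau <- 6.4e-6
  n <- 4096
  grid <- time_grid(tau, n + 1)
  f0 <- 2000
  delay <- 50e-6
  tt <- (seq_len(n) - 1) * tau
  tf <- synthetic_girf(3750, delay_s = delay, order = 2)
  y <- apply_girf(sin(2 * pi * f0 * tt), tf, grid)
  expected <- (1 + (f0 / 3750)^4)^(-0.5) * sin(2 * pi * f0 * (tt - delay))
  interior <- 500:3500
  expect_lt(max(abs(y[interior] - expected[interior])), 1e-3)
})

test_that("time invariance holds in the padded interior", {
  grid <- time_grid(6.4e-6, 257)
  tf <- synthetic_girf(4000, delay_s = 30e-6)
  pulse <- exp(-((1:256) - 60)^2 / 50)
  shifted <- c(rep(0, 40), pulse[1:216])
  y1 <- apply_girf(pulse, tf, grid)
  y2 <- apply_girf(shifted, tf, grid)
  expect_lt(max(abs(y2[61:200] - y1[21:160])), 1e-9)
})

test_that("cutoff frequency finds the half-magnitude point", {
  expect_true(is.na(cutoff_frequency(ideal_girf())))
  # Butterworth magnitude hits exactly 1/2 at fc * 3^(1/(2*order))
  for (ord in c(1, 2)) {
    tf <- synthetic_girf(3000, order = ord, delta_f = 10)
    expect_equal(cutoff_frequency(tf), 3000 * 3^(1 / (2 * ord)),
                 tolerance = 1e-4)
  }
  # synthetic table emulating the measured z-axis response: cutoff ~3750 Hz
  hz <- synthetic_girf(3750 / 3^(1 / 4), order = 2, delta_f = 76.3,
                       label = "Hz_synth")
  expect_equal(cutoff_frequency(hz), 3750, tolerance = 1e-3)
  expect_equal(Mod(hz$H[1]), 1)
})

test_that("averaging transfer functions is a pointwise complex mean", {
  a <- synthetic_girf(4200, delay_s = 10e-6)
  b <- synthetic_girf(3750, delay_s = 40e-6)
  avg <- average_girfs(list(a, b), label = "Hyz")
  expect_equal(avg$H, (a$H + b$H) / 2)
  expect_equal(average_girfs(list(a, a))$H, a$H)
  one <- transfer_function(a$f, rep(1 + 0i, length(a$f)))
  zero <- transfer_function(a$f, rep(0 + 0i, length(a$f)))
  expect_equal(average_girfs(list(one, zero))$H,
               rep(0.5 + 0i, length(a$f)))
  short <- transfer_function(seq(0, 1000, by = 100), rep(1 + 0i, 11))
  expect_error(average_girfs(list(a, short)), "axes")
})

test_that("GIRF CSV save/load round trips and validates", {
  tf <- synthetic_girf(3750, delay_s = 50e-6, order = 2, label = "Hz_synth")
  f <- withr::local_tempfile(fileext = ".csv")
  save_girf(tf, f)
  back <- load_girf(f)
  expect_identical(back$f, tf$f)
  expect_identical(back$H, tf$H)
  expect_identical(back$label, "Hz_synth")
  # missing imaginary column warns and zeros
  writeLines(c("f_Hz,H_re", sprintf("%g,%g", tf$f[1:10], Re(tf$H[1:10]))),
             f)
  expect_warning(ld <- load_girf(f), "imaginary")
  expect_equal(Im(ld$H), rep(0, 10))
  # non-uniform axis is a format error
  writeLines(c("f_Hz,H_re,H_im", "0,1,0", "10,1,0", "30,1,0"), f)
  expect_error(load_girf(f), "uniform")
})

test_that("two-sided tables are made Hermitian on load", {
  f2 <- seq(-1000, 1000, by = 100)
  H2 <- complex(real = runif(21), imaginary = runif(21))  # not Hermitian
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("f_Hz,H_re,H_im",
               sprintf("%.10g,%.10g,%.10g", f2, Re(H2), Im(H2))), tmp)
  tf <- load_girf(tmp)
  H <- tf$H
  revi <- rev(seq_along(H))
  expect_equal(H, Conj(H[revi]), tolerance = 1e-12)
  # Hermitian H must produce a real filtered output
  grid <- time_grid(1e-4, 33)
  y <- apply_girf(rnorm(32), tf, grid)
  expect_true(all(is.finite(y)))
})
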