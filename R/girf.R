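#' Gradient system transfer function
#'
#' Tabulated complex frequency response `H(f)` of the gradient chain
#' (amplifier, coil, eddy currents) under the linear time-invariant
#' assumption.  The axis may be one-sided (`f >= 0`, Hermitian symmetry
#' implied) or two-sided symmetric about 0; it must be uniformly spaced.
#'
#' @param f frequency axis (Hz), uniformly spaced.
#' @param H complex response, same length as `f`.
#' @param label axis identifier, e.g. `"Hi"`, `"Hy"`, `"Hz"`, `"Hyz"`.
#' @return An object of class `transfer_function` with fields `f`, `H`,
#'   `delta_f`, `label`.
#' @export
transfer_function <- function(f, H, label = "H") {
  stopifnot(length(f) == length(H), length(f) >= 2L)
  if (any(!is.finite(f)) || any(!is.finite(Mod(H))))
    stop("non-finite transfer function entries")
  df <- diff(f)
  delta_f <- mean(df)
  if (delta_f <= 0 || any(abs(df - delta_f) > 1e-6 * abs(delta_f)))
    stop("frequency axis must be uniform and increasing")
  o <- list(f = as.numeric(f), H = as.complex(H),
            delta_f = delta_f, label = as.character(label))
  class(o) <- "transfer_function"
  o
}

#' @export
print.transfer_function <- function(x, ...) {
  fc <- cutoff_frequency(x)
  cat(sprintf("<transfer_function> %s: %d points, delta_f = %.4g Hz, f in [%g, %g] Hz, 1/2-cutoff %s\n",
              x$label, length(x$f), x$delta_f, min(x$f), max(x$f),
              if (is.na(fc)) "none in range" else sprintf("%.0f Hz", fc)))
  invisible(x)
}

#' Ideal (identity) gradient response
#'
#' `H == 1` on a one-sided axis; filtering with it returns the input.
#' @param bandwidth_Hz extent of the tabulated axis.
#' @param delta_f frequency resolution (Hz).
#' @export
ideal_girf <- function(bandwidth_Hz = 200e3, delta_f = 76.3) {
  f <- seq(0, bandwidth_Hz, by = delta_f)
  transfer_function(f, rep(1 + 0i, length(f)), label = "Hi")
}

#' Synthetic low-pass GIRF
#'
#' Butterworth-like magnitude with a pure delay phase, emulating the
#' low-pass character and frequency-dependent phase shift of a measured
#' gradient chain:
#' `|H(f)| = (1 + (f/cutoff)^(2*order))^(-1/2)`, `arg H(f) = -2*pi*f*delay`.
#'
#' @param cutoff_Hz frequency where the magnitude falls to `1/sqrt(2)`.
#' @param delay_s group delay in seconds.
#' @param order filter order (>= 1).
#' @param delta_f tabulation resolution (Hz).
#' @param bandwidth_Hz extent of the tabulated (one-sided) axis; must
#'   exceed `cutoff_Hz`.
#' @param label axis identifier.
#' @return A [transfer_function()].
#' @export
synthetic_girf <- function(cutoff_Hz, delay_s = 0, order = 1,
                           delta_f = 76.3, bandwidth_Hz = 200e3,
                           label = "Hsynth") {
  stopifnot(cutoff_Hz > 0, order >= 1)
  if (cutoff_Hz >= bandwidth_Hz)
    stop("cutoff beyond the declared bandwidth")
  f <- seq(0, bandwidth_Hz, by = delta_f)
  mag <- (1 + (f / cutoff_Hz)^(2 * order))^(-0.5)
  transfer_function(f, mag * exp(-2i * pi * f * delay_s), label = label)
}

#' Pointwise average of transfer functions
#'
#' Arithmetic complex mean; used e.g. to form a direction-averaged response
#' from the y- and z-axis GIRFs.
#'
#' @param tfs list of [transfer_function()] on identical frequency axes.
#' @param label identifier of the result.
#' @export
average_girfs <- function(tfs, label = "Havg") {
  stopifnot(length(tfs) >= 1L)
  f0 <- tfs[[1L]]$f
  for (tf in tfs) {
    if (length(tf$f) != length(f0) || any(abs(tf$f - f0) > 1e-6 * max(abs(f0), 1)))
      stop("frequency axes must match")
  }
  H <- Reduce(`+`, lapply(tfs, `[[`, "H")) / length(tfs)
  transfer_function(f0, H, label = label)
}

#' 1/2-magnitude cutoff frequency
#'
#' Smallest positive frequency at which `|H(f)| / |H(0)|` drops to 1/2,
#' linearly interpolated between tabulated points.  Returns `NA` when the
#' magnitude never falls below 1/2 within the tabulated range (e.g. for the
#' ideal response).
#'
#' @param tf a [transfer_function()].
#' @return Cutoff in Hz, or `NA_real_`.
#' @export
cutoff_frequency <- function(tf) {
  pos <- tf$f >= 0
  f <- tf$f[pos]; mag <- Mod(tf$H)[pos]
  o <- order(f)
  f <- f[o]; mag <- mag[o]
  m0 <- mag[which.min(abs(f))]
  if (m0 <= 0) stop("|H(0)| must be positive")
  rel <- mag / m0
  below <- which(rel <= 0.5)
  if (length(below) == 0L) return(NA_real_)
  k <- below[1L]
  if (k == 1L) return(f[1L])
  # linear interpolation between the bracketing samples
  f[k - 1L] + (0.5 - rel[k - 1L]) * (f[k] - f[k - 1L]) / (rel[k] - rel[k - 1L])
}

# Interpolate H onto signed FFT frequencies, Hermitian-symmetric, zero
# outside the tabulated support (the measured response is low-pass).
girf_on_fft_grid <- function(tf, freqs) {
  ip <- function(v, at) {
    y <- stats::approx(tf$f, v, xout = at, rule = 1)$y
    y[is.na(y)] <- 0
    y
  }
  if (any(tf$f < 0)) {
    H <- complex(real = ip(Re(tf$H), freqs), imaginary = ip(Im(tf$H), freqs))
    Hm <- complex(real = ip(Re(tf$H), -freqs), imaginary = ip(Im(tf$H), -freqs))
    (H + Conj(Hm)) / 2            # Hermitian average: real filtered output
  } else {
    af <- abs(freqs)
    re <- ip(Re(tf$H), af)
    im <- ip(Im(tf$H), af)
    complex(real = re, imaginary = ifelse(freqs < 0, -im, im))
  }
}

#' Apply a GIRF to a gradient waveform
#'
#' Realized gradient `Gt = Re(F^-1 H F Gs)`: the demanded waveform is
#' zero-padded to at least twice its length (next power of two), Fourier
#' transformed, multiplied by `H` interpolated onto the transform
#' frequencies (zero outside the tabulated support, Hermitian-symmetric),
#' inverse transformed, and truncated.  Zero padding reflects the gradient
#' being off before and after the pulse.
#'
#' @param grad a [gradient_waveform()] or a bare numeric vector (T/m).
#' @param tf a [transfer_function()].
#' @param grid the [time_grid()] (required when `grad` is a bare vector).
#' @return Realized gradient samples (T/m), same length as the input.
#' @export
apply_girf <- function(grad, tf, grid = NULL) {
  if (inherits(grad, "gradient_waveform")) {
    grid <- grad$grid
    g <- grad$Gs
  } else {
    stopifnot(inherits(grid, "time_grid"))
    g <- as.numeric(grad)
  }
  girf_filter_closure(tf, grid, length(g))$forward(g)
}

# FFT filtering kernel shared by apply_girf and its adjoint.  The sampled H
# depends only on (tf, tau, n), so it is cached per call site by
# girf_operator(); results are identical with or without the cache.
girf_filter_closure <- function(tf, grid, n) {
  npad <- 2^ceiling(log2(max(2 * n, 2)))
  freqs <- c(seq(0, npad / 2), seq(-npad / 2 + 1, -1)) / (npad * grid$tau)
  Hs <- girf_on_fft_grid(tf, freqs)
  list(
    forward = function(g) {
      G <- stats::fft(c(g, rep(0, npad - length(g))))
      Re(stats::fft(G * Hs, inverse = TRUE) / npad)[seq_along(g)]
    },
    adjoint = function(y) {
      Y <- stats::fft(c(y, rep(0, npad - length(y))))
      Re(stats::fft(Y * Conj(Hs), inverse = TRUE) / npad)[seq_along(y)]
    }
  )
}

#' Discrete GIRF filter operator and its transpose
#'
#' Dense matrix representation of the linear map `Gs -> Re(F^-1 H F Gs)` on
#' sequences of length `nt - 1`, with its transpose for adjoint (chain
#' rule) computations.  Column `m` equals [apply_girf()] of the m-th unit
#' impulse.
#'
#' @param tf a [transfer_function()].
#' @param grid a [time_grid()].
#' @return A list of class `girf_operator` with fields `A` (matrix), `At`
#'   (its transpose), `forward` and `adjoint` (FFT-based applications).
#' @export
girf_filter_matrix <- function(tf, grid) {
  n <- n_intervals(grid)
  ker <- girf_filter_closure(tf, grid, n)
  A <- matrix(0, n, n)
  for (m in seq_len(n)) {
    e <- numeric(n); e[m] <- 1
    A[, m] <- ker$forward(e)
  }
  structure(list(A = A, At = t(A), forward = ker$forward,
                 adjoint = ker$adjoint),
            class = "girf_operator")
}

#' Write a transfer function to CSV
#'
#' Columns `f_Hz`, `H_re`, `H_im` with a header comment recording
#' `delta_f`; the interchange format read by [load_girf()].
#'
#' @param tf a [transfer_function()].
#' @param file path to write.
#' @export
save_girf <- function(tf, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# girf delta_f=%.17g label=%s", tf$delta_f, tf$label), con)
  writeLines("f_Hz,H_re,H_im", con)
  writeLines(sprintf("%.17g,%.17g,%.17g", tf$f, Re(tf$H), Im(tf$H)), con)
  invisible(file)
}

#' Load a tabulated GIRF
#'
#' Reads a CSV with columns `f_Hz`, `H_re`, `H_im` (a missing `H_im` column
#' is treated as zero with a warning).  The frequency axis must be uniform
#' to a relative tolerance of 1e-6.  For a two-sided axis, Hermitian
#' symmetry is enforced by averaging `H(f)` with `Conj(H(-f))`.
#'
#' @param file path to a GIRF CSV.
#' @param label axis identifier; defaults to the label recorded in the
#'   file header, if any.
#' @return A [transfer_function()].
#' @export
load_girf <- function(file, label = NULL) {
  header <- readLines(file, n = 1L)
  if (is.null(label)) {
    m <- regmatches(header, regexec("label=([^ ,]+)", header))[[1]]
    label <- if (length(m) == 2L) m[2] else "H"
  }
  d <- utils::read.csv(file, comment.char = "#", header = TRUE)
  if (!all(c("f_Hz", "H_re") %in% names(d)))
    stop("GIRF file must supply columns f_Hz and H_re")
  if (is.null(d$H_im)) {
    warning("no H_im column; imaginary part treated as zero")
    d$H_im <- 0
  }
  f <- d$f_Hz
  H <- complex(real = d$H_re, imaginary = d$H_im)
  if (any(f < 0)) {
    # enforce Hermitian symmetry of the two-sided table
    o <- order(f)
    f <- f[o]; H <- H[o]
    Hm <- stats::approx(f, Re(H), xout = -f, rule = 2)$y +
      1i * stats::approx(f, Im(H), xout = -f, rule = 2)$y
    H <- (H + Conj(Hm)) / 2
  }
  transfer_function(f, H, label = label)
}
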