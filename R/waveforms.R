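#' Uniform time raster
#'
#' Waveforms are piecewise constant on `nt - 1` intervals of width `tau`;
#' the total duration is `T = (nt - 1) * tau`.
#'
#' @param tau raster step in seconds (e.g. `6.4e-6` for a 6.4 us gradient
#'   raster).
#' @param nt number of time grid points (`nt >= 2`).
#' @return An object of class `time_grid` with fields `tau`, `nt`, `T`.
#' @examples
#' g <- time_grid(6.4e-6, 101)
#' g$T  # 100 intervals -> 640 us
#' @export
time_grid <- function(tau, nt) {
  stopifnot(is.numeric(tau), length(tau) == 1L, tau > 0)
  nt <- as.integer(nt)
  if (is.na(nt) || nt < 2L) stop("'nt' must be an integer >= 2")
  structure(list(tau = tau, nt = nt, T = (nt - 1L) * tau), class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> tau = %.6g us, nt = %d, T = %.6g ms\n",
              x$tau * 1e6, x$nt, x$T * 1e3))
  invisible(x)
}

n_intervals <- function(grid) grid$nt - 1L

#' RF waveform in polar form
#'
#' Piecewise-constant complex RF `B1_m = r_m * exp(1i * theta_m)` on the
#' intervals of a [time_grid()].  Amplitudes are stored in tesla; `r` is
#' non-negative and `theta` lies in `[-pi, pi]`.  With `real_valued = TRUE`
#' the phase is restricted to `{0, pi}`, i.e. the pulse is a signed real
#' waveform (the design mode used for all refocusing examples).
#'
#' @param r amplitude per interval (T), length `nt - 1`.
#' @param theta phase per interval (rad), recycled if length 1.
#' @param grid a [time_grid()].
#' @param real_valued restrict phases to `{0, pi}`.
#' @return An object of class `rf_waveform`.
#' @export
rf_waveform <- function(r, theta = 0, grid, real_valued = TRUE) {
  stopifnot(inherits(grid, "time_grid"))
  n <- n_intervals(grid)
  if (length(r) != n) stop("'r' must have length nt - 1")
  theta <- rep_len(theta, n)
  if (any(!is.finite(r)) || any(!is.finite(theta)))
    stop("non-finite RF samples")
  if (any(r < 0)) stop("'r' must be non-negative; use theta = pi for sign")
  if (real_valued && any(abs(sin(theta)) > 1e-12))
    stop("real_valued RF requires theta in {0, pi}")
  structure(list(r = as.numeric(r), theta = as.numeric(theta),
                 grid = grid, real_valued = isTRUE(real_valued)),
            class = "rf_waveform")
}

#' Complex RF samples of an rf_waveform
#' @param rf an [rf_waveform()].
#' @return Complex vector `r * exp(1i * theta)` (T), length `nt - 1`.
#' @export
rf_complex <- function(rf) rf$r * exp(1i * rf$theta)

#' Signed real RF samples
#'
#' For a `real_valued` waveform, returns `r * cos(theta)` (theta in
#' `{0, pi}` maps to a sign).
#' @param rf an [rf_waveform()].
#' @export
rf_signed <- function(rf) rf$r * cos(rf$theta)

#' @export
print.rf_waveform <- function(x, ...) {
  cat(sprintf("<rf_waveform> %d samples, peak %.3f uT, %s\n",
              length(x$r), max(x$r) * 1e6,
              if (x$real_valued) "real-valued" else "complex"))
  invisible(x)
}

#' Slice-selective gradient waveform
#'
#' Demanded gradient amplitude `Gs` (T/m) per interval together with the slew
#' sequence `s` (T/m/s) that generates it: `Gs_m - Gs_{m-1} = tau * s_m`
#' with the implicit start value `Gs_0 = 0`.
#'
#' @param Gs gradient per interval (T/m), length `nt - 1`.
#' @param grid a [time_grid()].
#' @return An object of class `gradient_waveform` with fields `Gs`, `s`.
#' @seealso [integrate_slew()] for the inverse construction from a slew
#'   sequence.
#' @export
gradient_waveform <- function(Gs, grid) {
  stopifnot(inherits(grid, "time_grid"))
  n <- n_intervals(grid)
  if (length(Gs) != n) stop("'Gs' must have length nt - 1")
  if (any(!is.finite(Gs))) stop("non-finite gradient samples")
  s <- diff(c(0, Gs)) / grid$tau
  structure(list(Gs = as.numeric(Gs), s = s, grid = grid),
            class = "gradient_waveform")
}

#' @export
print.gradient_waveform <- function(x, ...) {
  cat(sprintf("<gradient_waveform> %d samples, peak %.3f mT/m, peak slew %.1f T/m/s\n",
              length(x$Gs), max(abs(x$Gs)) * 1e3, max(abs(x$s))))
  invisible(x)
}

#' Integrate a slew sequence into a gradient waveform
#'
#' `Gs_m = tau * sum_{k<=m} s_k`, starting from `Gs_0 = 0`.  This is the map
#' through which the optimizer's slew controls parameterize the gradient;
#' differencing the result recovers `s` exactly.
#'
#' @param s slew sequence (T/m/s), length `nt - 1`.
#' @param grid a [time_grid()].
#' @return A [gradient_waveform()].
#' @export
integrate_slew <- function(s, grid) {
  stopifnot(inherits(grid, "time_grid"))
  if (length(s) != n_intervals(grid))
    stop("'s' must have length nt - 1")
  gradient_waveform(grid$tau * cumsum(s), grid)
}

#' Hardware amplitude and slew limits
#'
#' @param rmax_uT peak RF amplitude (uT).
#' @param gmax_mT_m peak slice-selective gradient amplitude (mT/m).
#' @param smax_T_m_s peak gradient slew rate (T/m/s).
#' @return An object of class `hardware_bounds` storing SI values
#'   `rmax` (T), `gmax` (T/m), `smax` (T/m/s).
#' @examples
#' hardware_bounds()  # 13 uT, 30 mT/m, 180 T/m/s
#' @export
hardware_bounds <- function(rmax_uT = 13, gmax_mT_m = 30, smax_T_m_s = 180) {
  stopifnot(rmax_uT > 0, gmax_mT_m > 0, smax_T_m_s > 0)
  structure(list(rmax = rmax_uT * 1e-6, gmax = gmax_mT_m * 1e-3,
                 smax = smax_T_m_s),
            class = "hardware_bounds")
}

#' @export
print.hardware_bounds <- function(x, ...) {
  cat(sprintf("<hardware_bounds> rmax = %g uT, Gmax = %g mT/m, smax = %g T/m/s\n",
              x$rmax * 1e6, x$gmax * 1e3, x$smax))
  invisible(x)
}

#' Control vector (r, theta, s)
#'
#' The optimization controls: RF amplitude `r` (T), RF phase `theta` (rad)
#' and gradient slew `s` (T/m/s), each of length `nt - 1`.  The gradient
#' itself is a state derived by [integrate_slew()].
#'
#' @param r,theta,s numeric vectors of equal length.
#' @param grid the [time_grid()] the controls live on.
#' @param real_valued logical; signed real RF (theta restricted to `{0, pi}`).
#' @export
control_vector <- function(r, theta, s, grid, real_valued = TRUE) {
  stopifnot(inherits(grid, "time_grid"))
  n <- n_intervals(grid)
  if (length(r) != n || length(theta) != n || length(s) != n)
    stop("control components must all have length nt - 1")
  structure(list(r = as.numeric(r), theta = as.numeric(theta),
                 s = as.numeric(s), grid = grid,
                 real_valued = isTRUE(real_valued)),
            class = "control_vector")
}

#' Project controls onto the hard hardware box
#'
#' Component-wise clamp of `r` into `[0, rmax]`, `s` into `[-smax, smax]`
#' and `theta` into `[-pi, pi]`.  Idempotent and non-expansive.  The
#' demanded gradient amplitude bound `Gmax` is a state constraint handled by
#' the objective's gradient penalty, not by this projection.
#'
#' @param x a [control_vector()].
#' @param bounds a [hardware_bounds()].
#' @return The projected [control_vector()].
#' @export
project_controls <- function(x, bounds) {
  stopifnot(inherits(x, "control_vector"), inherits(bounds, "hardware_bounds"))
  x$r <- pmin(pmax(x$r, 0), bounds$rmax)
  x$theta <- pmin(pmax(x$theta, -pi), pi)
  x$s <- pmin(pmax(x$s, -bounds$smax), bounds$smax)
  x
}

#' Resample controls onto a grid with a different number of points
#'
#' Maps a candidate design onto a shorter (or longer) raster of the same
#' step `tau`, then projects onto the bounds.  Two interpolation notions
#' are offered:
#' \describe{
#'   \item{`"amplitude"`}{controls linearly interpolated in normalized
#'     time (interval midpoints mapped to `[0, 1]`); a constant stays the
#'     same constant and a ramp keeps its endpoints.}
#'   \item{`"moment"`}{the cumulative integrals of the signed RF and of
#'     the gradient are interpolated instead, so flip areas and gradient
#'     moments (hence slice positions) are preserved while the waveform
#'     compresses; amplitudes scale by the compression ratio before
#'     projection.  This is the warm start used by the minimum-duration
#'     search -- compressing amplitudes instead would dilate the k-space
#'     comb and move every slice.}
#' }
#'
#' @param x a [control_vector()] on `grid_old`.
#' @param grid_new target [time_grid()] with the same `tau`.
#' @param bounds a [hardware_bounds()] used for the final projection.
#' @param preserve `"amplitude"` or `"moment"` (see above).
#' @return A [control_vector()] on `grid_new`.
#' @export
resample_controls <- function(x, grid_new, bounds,
                              preserve = c("amplitude", "moment")) {
  stopifnot(inherits(x, "control_vector"), inherits(grid_new, "time_grid"))
  preserve <- match.arg(preserve)
  if (abs(grid_new$tau - x$grid$tau) > 1e-12 * x$grid$tau)
    stop("resampling changes nt only; 'tau' must match")
  n_old <- length(x$r)
  n_new <- n_intervals(grid_new)
  if (n_new < 1L) stop("new grid must have at least one interval")
  if (n_new == n_old) return(project_controls(x, bounds))
  tau <- x$grid$tau
  u_old <- x$r * cos(x$theta)
  v_old <- x$r * sin(x$theta)
  if (preserve == "amplitude") {
    t_old <- (seq_len(n_old) - 0.5) / n_old
    t_new <- (seq_len(n_new) - 0.5) / n_new
    ip <- function(w) stats::approx(t_old, w, xout = t_new, rule = 2)$y
    u <- ip(u_old)
    v <- ip(v_old)
    Gs_new <- ip(tau * cumsum(x$s))
    s_new <- diff(c(0, Gs_new)) / tau
  } else {
    # interpolate cumulative integrals at normalized knot times
    t_old <- (0:n_old) / n_old
    t_new <- (0:n_new) / n_new
    cum <- function(w) stats::approx(t_old, c(0, cumsum(w)) * tau,
                                     xout = t_new, rule = 2)$y
    u <- diff(cum(u_old)) / tau
    v <- diff(cum(v_old)) / tau
    # gradient: preserve the k-space trajectory (cumulative moment of Gs)
    Gs_old <- tau * cumsum(x$s)
    Gs_new <- diff(cum(Gs_old)) / tau
    s_new <- diff(c(0, Gs_new)) / tau
  }
  r_new <- sqrt(u^2 + v^2)
  th_new <- atan2(v, u)
  if (x$real_valued) th_new <- ifelse(cos(th_new) >= 0, 0, pi)
  project_controls(control_vector(r_new, th_new, s_new, grid_new,
                                  real_valued = x$real_valued),
                   bounds)
}

#' Write RF and gradient waveforms to a columnar text file
#'
#' Three (real RF) or four (complex RF) column CSV with a `#`-prefixed
#' header recording `tau` and `nt`.  Values are stored in SI units (T,
#' T/m) with 17 significant digits, so a read/write round trip reproduces
#' the stored doubles bit-exactly; converting to the display units (uT,
#' mT/m) is left to the reader because the conversion itself costs an ulp.
#'
#' @param rf an [rf_waveform()].
#' @param grad a [gradient_waveform()] on the same grid.
#' @param file path to write.
#' @export
write_waveform_csv <- function(rf, grad, file) {
  stopifnot(inherits(rf, "rf_waveform"), inherits(grad, "gradient_waveform"))
  n <- length(rf$r)
  if (length(grad$Gs) != n) stop("rf and grad must share a grid")
  tau <- rf$grid$tau
  t_s <- (seq_len(n) - 1L) * tau
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# girfpulse waveform tau_s=%.17g nt=%d real_valued=%d units=T,T/m",
                     tau, rf$grid$nt, as.integer(rf$real_valued)), con)
  if (rf$real_valued) {
    writeLines("time_s,rf_T,grad_T_per_m", con)
    writeLines(sprintf("%.17g,%.17g,%.17g", t_s,
                       rf_signed(rf), grad$Gs), con)
  } else {
    writeLines("time_s,rf_re_T,rf_im_T,grad_T_per_m", con)
    b1 <- rf_complex(rf)
    writeLines(sprintf("%.17g,%.17g,%.17g,%.17g", t_s,
                       Re(b1), Im(b1), grad$Gs), con)
  }
  invisible(file)
}

#' Read waveforms written by [write_waveform_csv()]
#'
#' @param file path to a waveform CSV.
#' @return A list with components `rf` ([rf_waveform()]), `grad`
#'   ([gradient_waveform()]) and `grid` ([time_grid()]).
#' @export
read_waveform_csv <- function(file) {
  header <- readLines(file, n = 1L)
  m <- regmatches(header, regexec(
    "tau_s=([0-9.eE+-]+) nt=([0-9]+) real_valued=([01])", header))[[1]]
  if (length(m) != 4L) stop("not a girfpulse waveform file: ", file)
  tau <- as.numeric(m[2]); nt <- as.integer(m[3]); realv <- m[4] == "1"
  d <- utils::read.csv(file, comment.char = "#", header = TRUE)
  grid <- time_grid(tau, nt)
  if (nrow(d) != nt - 1L) stop("sample count does not match header nt")
  if (realv) {
    u <- d$rf_T
    rf <- rf_waveform(abs(u), ifelse(u >= 0, 0, pi), grid, real_valued = TRUE)
  } else {
    b1 <- complex(real = d$rf_re_T, imaginary = d$rf_im_T)
    rf <- rf_waveform(Mod(b1), Arg(b1), grid, real_valued = FALSE)
  }
  list(rf = rf, grad = gradient_waveform(d$grad_T_per_m, grid),
       grid = grid)
}
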