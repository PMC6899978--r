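#' Slice specification and spatial domain decomposition
#'
#' `mb` slices of thickness `thk_m`, evenly distributed across the design
#' field of view (center-to-center spacing `fov_m / mb`).  Every spatial
#' point is assigned to exactly one of: in-slice (within
#' `(thk/2)*(1 - ftw)` of a slice center), transition band (between
#' `(thk/2)*(1 - ftw)` and `(thk/2)*(1 + ftw)`), or out-of-slice.  The
#' transition half-width tracks the SLR prototype's fractional transition
#' width `ftw`, so the constrained domains match what the sub-pulse can
#' deliver.
#'
#' @param mb multiband factor (number of slices).
#' @param thk_m slice thickness (m).
#' @param fov_m design field of view (m).
#' @param tbwp time-bandwidth product of the sub-pulse.
#' @param space a [spatial_grid()].
#' @param ftw fractional transition width; default is the SLR estimate
#'   `min(d_inf(d1/4, sqrt(d2)) / tbwp, 0.9)` used by
#'   [design_slr_subpulse()].
#' @param d1,d2 profile ripples used for the default `ftw`.
#' @return An object of class `slice_spec` with fields `centers`,
#'   `in_slice` (logical per z), `out_slice`, `transition`, `slice_index`
#'   (integer per z, NA outside in-slice sets), plus the inputs.
#' @export
build_slice_domains <- function(mb, thk_m, fov_m, tbwp, space,
                                ftw = NULL, d1 = 0.01 / 4, d2 = 0.01 / 2) {
  stopifnot(inherits(space, "spatial_grid"), mb >= 1, thk_m > 0)
  if (mb * thk_m >= fov_m)
    stop("slices do not fit: mb * thk must be smaller than the FOV")
  if (is.null(ftw)) ftw <- min(d_inf(d1 / 4, sqrt(d2)) / tbwp, 0.9)
  spacing <- fov_m / mb
  centers <- (seq_len(mb) - (mb + 1) / 2) * spacing
  r_in <- (thk_m / 2) * (1 - ftw)
  r_out <- (thk_m / 2) * (1 + ftw)
  if (2 * r_out >= spacing)
    stop("slices overlap after adding transition bands")
  dist <- vapply(space$z, function(zz) min(abs(zz - centers)), numeric(1))
  nearest <- vapply(space$z, function(zz) which.min(abs(zz - centers)), integer(1))
  in_slice <- dist <= r_in
  transition <- !in_slice & dist < r_out
  out_slice <- !in_slice & !transition
  slice_index <- ifelse(in_slice, nearest, NA_integer_)
  owned <- tabulate(slice_index[!is.na(slice_index)], nbins = mb)
  if (any(owned == 0L))
    stop("slice ", which(owned == 0L)[1L], " owns no in-slice grid point; ",
         "use a finer spatial grid or a smaller transition width")
  structure(list(mb = mb, thk = thk_m, fov = fov_m, tbwp = tbwp,
                 spacing = spacing, centers = centers, ftw = ftw,
                 r_in = r_in, r_out = r_out,
                 in_slice = in_slice, out_slice = out_slice,
                 transition = transition, slice_index = slice_index,
                 space = space),
            class = "slice_spec")
}

#' @export
print.slice_spec <- function(x, ...) {
  cat(sprintf("<slice_spec> MB = %d, THK = %.2f mm, FOV = %.0f mm, TBWP = %g, ftw = %.3f\n",
              x$mb, x$thk * 1e3, x$fov * 1e3, x$tbwp, x$ftw))
  cat(sprintf("  z points: %d in-slice, %d transition, %d out-of-slice\n",
              sum(x$in_slice), sum(x$transition), sum(x$out_slice)))
  invisible(x)
}

# Minimum-time half-sine gradient blip with zeroth moment `area` (T s / m)
# on the raster, slew-limited; falls back to a sine-ramp trapezoid when the
# half-sine peak would exceed gmax.  Amplitudes are rescaled after raster
# rounding so the moment is exact.
min_time_blip <- function(area, bounds, tau) {
  stopifnot(area > 0)
  tb <- pi * sqrt(area / (2 * bounds$smax))
  gp <- bounds$smax * tb / pi
  if (gp <= bounds$gmax) {
    n <- max(2L, as.integer(ceiling(tb / tau)))
    repeat {
      shape <- sin(pi * (seq_len(n) - 0.5) / n)
      g <- shape * area / (tau * sum(shape))
      slew <- max(abs(diff(c(0, g, 0)))) / tau
      if (slew <= bounds$smax && max(g) <= bounds$gmax) break
      n <- n + 1L
    }
    return(g)
  }
  # quarter-sine ramps to gmax, flat top
  tr <- pi * bounds$gmax / (2 * bounds$smax)
  ramp_area <- bounds$gmax * 2 * tr / pi
  if (2 * ramp_area > area)
    stop("blip area unreachable under the given hardware bounds")
  nr <- max(1L, as.integer(ceiling(tr / tau)))
  nf <- as.integer(ceiling((area - 2 * ramp_area) / (bounds$gmax * tau)))
  up <- sin(pi * (seq_len(nr) - 0.5) / (2 * nr))
  shape <- c(up, rep(1, nf), rev(up))
  g <- shape * area / (tau * sum(shape))
  if (max(abs(diff(c(0, g, 0)))) / tau > bounds$smax || max(g) > bounds$gmax)
    stop("blip area unreachable under the given hardware bounds")
  g
}

#' PINS initialization: SLR sub-pulse train with gradient blips
#'
#' Builds the power-independent-of-number-of-slices (PINS) refocusing pulse
#' used to initialize the optimal-control design: `n` hard RF sub-pulses
#' (the SLR hard-pulse flips, `n = ceiling(TBWP * spacing / THK)`)
#' interleaved with `n - 1` minimum-time gradient blips whose zeroth moment
#' advances the precession phase by exactly one cycle per slice spacing.
#' RF is off during blips and the gradient is zero during RF, so the
#' on-resonance profile equals the SLR polynomial's frequency response
#' exactly.  All sub-pulses share the duration dictated by the largest flip
#' at `rmax` (rounded up to the raster); for even `mb` the flips alternate
#' in sign, shifting the slice comb by half a period so the pattern is
#' symmetric about the isocenter.
#'
#' @param mb multiband factor.
#' @param tbwp time-bandwidth product.
#' @param thk_m slice thickness (m).
#' @param fov_m design field of view (m).
#' @param bounds a [hardware_bounds()].
#' @param tau raster time (s).
#' @param d1,d2 crushed-SE profile ripples of the SLR sub-pulse.
#' @return A list of class `pins_pulse` with `rf` ([rf_waveform()]),
#'   `grad` ([gradient_waveform()]), `grid` ([time_grid()]), the
#'   `slr_design`, the per-component sample counts and `duration_ms`.
#' @examples
#' p <- build_pins(3, 2, 2e-3, 120e-3, hardware_bounds(), 6.4e-6)
#' p$duration_ms
#' @export
build_pins <- function(mb, tbwp, thk_m, fov_m, bounds = hardware_bounds(),
                       tau = 6.4e-6, d1 = 0.01 / 4, d2 = 0.01 / 2) {
  stopifnot(inherits(bounds, "hardware_bounds"), tau > 0)
  spacing <- fov_m / mb
  if (mb * thk_m >= fov_m) stop("slices do not fit inside the FOV")
  n <- as.integer(ceiling(tbwp * spacing / thk_m))
  slr <- design_slr_subpulse(tbwp, d1 = d1, d2 = d2, n_samples = n)
  flips <- slr$flips
  if (mb %% 2L == 0L) flips <- flips * (-1)^(seq_len(n) - 1L)
  area <- 2 * pi / (GAMMA_1H * spacing)   # one precession cycle per spacing
  blip <- min_time_blip(area, bounds, tau)
  n_sub <- as.integer(ceiling(max(abs(flips)) / (GAMMA_1H * bounds$rmax * tau)))
  amp <- flips / (GAMMA_1H * n_sub * tau)          # signed amplitude (T)
  n_tot <- n * n_sub + (n - 1L) * length(blip)
  rf_s <- numeric(n_tot)
  g_s <- numeric(n_tot)
  pos <- 0L
  for (k in seq_len(n)) {
    rf_s[pos + seq_len(n_sub)] <- amp[k]
    pos <- pos + n_sub
    if (k < n) {
      g_s[pos + seq_along(blip)] <- blip
      pos <- pos + length(blip)
    }
  }
  grid <- time_grid(tau, n_tot + 1L)
  rf <- rf_waveform(abs(rf_s), ifelse(rf_s >= 0, 0, pi), grid,
                    real_valued = TRUE)
  grad <- gradient_waveform(g_s, grid)
  structure(list(rf = rf, grad = grad, grid = grid, slr = slr,
                 mb = mb, tbwp = tbwp, thk = thk_m, fov = fov_m,
                 spacing = spacing, n_subpulses = n, n_sub_samples = n_sub,
                 n_blip_samples = length(blip),
                 duration_ms = grid$T * 1e3),
            class = "pins_pulse")
}

#' @export
print.pins_pulse <- function(x, ...) {
  cat(sprintf("<pins_pulse> MB = %d, TBWP = %g, THK = %.1f mm, FOV = %.0f mm\n",
              x$mb, x$tbwp, x$thk * 1e3, x$fov * 1e3))
  cat(sprintf("  %d sub-pulses x %d samples + %d blips x %d samples -> T = %.3f ms\n",
              x$n_subpulses, x$n_sub_samples, x$n_subpulses - 1L,
              x$n_blip_samples, x$duration_ms))
  invisible(x)
}
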