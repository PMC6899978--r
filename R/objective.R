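#' Slice-profile error bounds
#'
#' Magnitude error bounds for the refocusing profile (`|b|^2 <= e_out`
#' out-of-slice, `1 - |b|^2 <= e_in` in-slice) and the per-slice phase
#' half-width `e_p` for `arg(b^2)`.  Scalars are the common case (`es`);
#' per-z vectors are accepted.
#'
#' @param es scalar magnitude bound used for both `e_in` and `e_out`
#'   (e.g. 0.02 for 2%).
#' @param ep_rad allowed deviation of the in-slice phase from the slice
#'   mean (rad).
#' @param e_in,e_out optional separate (possibly per-z) bounds overriding
#'   `es`.
#' @export
profile_bounds <- function(es = 0.02, ep_rad = 0.025,
                           e_in = NULL, e_out = NULL) {
  if (is.null(e_in)) e_in <- es
  if (is.null(e_out)) e_out <- es
  stopifnot(all(e_in > 0), all(e_out > 0), ep_rad > 0, ep_rad < pi)
  structure(list(e_in = e_in, e_out = e_out, ep = ep_rad,
                 es = max(c(e_in, e_out))),
            class = "profile_bounds")
}

#' Penalty weights and exponent for the Lp-penalized profile constraints
#'
#' @param mu_rf RF energy weight.
#' @param mu_g demanded-gradient amplitude penalty weight.
#' @param mu_out,mu_in out-of-slice / in-slice magnitude penalty weights.
#' @param mu_p phase-spread penalty weight.
#' @param p even exponent `>= 2`; raised during the optimization toward
#'   L-infinity-like behaviour (see [continue_p()]).
#' @export
penalty_state <- function(mu_rf = 1e-6, mu_g = 1, mu_out = 1, mu_in = 1,
                          mu_p = 1, p = 2) {
  if (p %% 2 != 0 || p < 2) stop("'p' must be an even integer >= 2")
  w <- c(mu_rf, mu_g, mu_out, mu_in, mu_p)
  if (any(w <= 0)) stop("penalty weights must be positive")
  structure(list(mu_rf = mu_rf, mu_g = mu_g, mu_out = mu_out,
                 mu_in = mu_in, mu_p = mu_p, p = as.integer(p),
                 n_adapt = 0L),
            class = "penalty_state")
}

#' SAR model constants
#'
#' The tracked global SAR estimate is
#' `SARe = coil_eff * fp * tau * sum(r_uT^2)` for a constant pulse
#' repetition rate `fp` and coil efficiency in W/kg/uT^2.
#'
#' @param fp_hz pulse rate (1/s).
#' @param coil_eff_w_kg_uT2 coil efficiency (W/kg/uT^2).
#' @param sar_max_w_kg SAR limit (W/kg); exceeding it doubles the RF
#'   energy weight at adaptation time.
#' @export
sar_config <- function(fp_hz = 16.67, coil_eff_w_kg_uT2 = 0.25,
                       sar_max_w_kg = 3.2) {
  stopifnot(fp_hz > 0, coil_eff_w_kg_uT2 > 0, sar_max_w_kg > 0)
  structure(list(fp = fp_hz, coil_eff = coil_eff_w_kg_uT2,
                 sar_max = sar_max_w_kg),
            class = "sar_config")
}

#' Global SAR estimate of an RF pulse
#'
#' @param rf an [rf_waveform()].
#' @param grid its [time_grid()] (defaults to the waveform's own grid).
#' @param cfg a [sar_config()].
#' @return SAR estimate in W/kg.
#' @export
sar_estimate <- function(rf, grid = rf$grid, cfg = sar_config()) {
  stopifnot(inherits(rf, "rf_waveform"), inherits(cfg, "sar_config"))
  r_uT <- rf$r * 1e6
  cfg$coil_eff * cfg$fp * grid$tau * sum(r_uT^2)
}

#' Signed magnitude-constraint violations per spatial point
#'
#' Out-of-slice points return `|b|^2 - e_out`; in-slice points
#' `(1 - |b|^2) - e_in`; transition-band points 0.  Positive values are
#' violations.
#'
#' @param magnitude `|b|^2` per z.
#' @param spec a [build_slice_domains()] result.
#' @param pbounds a [profile_bounds()].
#' @export
magnitude_violations <- function(magnitude, spec, pbounds) {
  stopifnot(length(magnitude) == spec$space$nz)
  v <- numeric(length(magnitude))
  e_out <- rep_len(pbounds$e_out, length(magnitude))
  e_in <- rep_len(pbounds$e_in, length(magnitude))
  v[spec$out_slice] <- magnitude[spec$out_slice] - e_out[spec$out_slice]
  v[spec$in_slice] <- (1 - magnitude[spec$in_slice]) - e_in[spec$in_slice]
  v
}

# Wrap angles into (-pi, pi]
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  ifelse(y == -pi, pi, y)
}

# Mean in-slice phase per slice as the argument of the mean unit phasor
# (wrap-safe), plus the wrapped deviations.
slice_phase_stats <- function(phase, spec) {
  means <- rep(NA_real_, spec$mb)
  dev <- numeric(length(phase))
  for (l in seq_len(spec$mb)) {
    idx <- which(spec$slice_index == l)
    if (length(idx) == 0L) stop("slice ", l, " has no in-slice points")
    means[l] <- Arg(mean(exp(1i * phase[idx])))
    dev[idx] <- wrap_angle(phase[idx] - means[l])
  }
  list(means = means, dev = dev)
}

#' Signed phase-constraint violations
#'
#' For every in-slice point of slice `l`, the violation is
#' `|wrap(phase - mean_l)| - e_p`, with the slice mean computed as the
#' argument of the mean in-slice unit phasor (safe across the branch cut).
#' Points outside the in-slice sets return 0.
#'
#' @param phase `arg(b^2)` per z (rad).
#' @param spec a [build_slice_domains()] result.
#' @param pbounds a [profile_bounds()].
#' @return Numeric vector of violations per z, with the per-slice mean
#'   phases attached as attribute `"mean_phase"`.
#' @export
phase_violations <- function(phase, spec, pbounds) {
  stopifnot(length(phase) == spec$space$nz)
  st <- slice_phase_stats(phase, spec)
  v <- numeric(length(phase))
  idx <- !is.na(spec$slice_index)
  v[idx] <- abs(st$dev[idx]) - pbounds$ep
  attr(v, "mean_phase") <- st$means
  v
}

#' Bundle of everything a design needs
#'
#' @param spec a [build_slice_domains()] result (which carries the spatial
#'   grid).
#' @param bounds a [hardware_bounds()].
#' @param pbounds a [profile_bounds()].
#' @param girf a [transfer_function()] used in the design loop, or `NULL`
#'   for the ideal (identity) response.
#' @param sar a [sar_config()].
#' @param real_valued design real-valued RF (the mode used throughout).
#' @param phase_constrained include the explicit per-slice phase-spread
#'   constraint; when `FALSE` only the magnitude profile is constrained.
#' @export
design_problem <- function(spec, bounds = hardware_bounds(),
                           pbounds = profile_bounds(), girf = NULL,
                           sar = sar_config(), real_valued = TRUE,
                           phase_constrained = TRUE) {
  stopifnot(inherits(spec, "slice_spec"))
  structure(list(spec = spec, space = spec$space, bounds = bounds,
                 pbounds = pbounds, girf = girf, sar = sar,
                 real_valued = isTRUE(real_valued),
                 phase_constrained = isTRUE(phase_constrained)),
            class = "design_problem")
}

# Realized gradient under the problem's design GIRF (identity when NULL);
# the returned closure carries the FFT kernel so repeated applications on
# the same grid reuse the interpolated H.
problem_filter <- function(problem, grid, n) {
  if (is.null(problem$girf)) {
    list(forward = identity, adjoint = identity)
  } else {
    girf_filter_closure(problem$girf, grid, n)
  }
}

# Forward evaluation shared by design_cost and cost_gradient.
forward_state <- function(x, problem, pen, keep_history = FALSE) {
  grid <- x$grid
  n <- n_intervals(grid)
  tau <- grid$tau
  flt <- problem_filter(problem, grid, n)
  Gs <- tau * cumsum(x$s)
  Gt <- flt$forward(Gs)
  b1 <- x$r * exp(1i * x$theta)
  p <- simulate_spin_domain(b1, Gt, grid, problem$space,
                            keep_history = keep_history)
  prof <- refocusing_profile(p)
  list(grid = grid, flt = flt, Gs = Gs, Gt = Gt, b1 = b1, profile = p,
       magnitude = prof$magnitude, phase = prof$phase)
}

# Cost terms given a forward state; returns J and the six-term breakdown.
cost_terms <- function(st, x, problem, pen) {
  grid <- st$grid
  tau <- grid$tau
  p <- pen$p
  spec <- problem$spec
  pb <- problem$pbounds
  delta <- problem$space$delta
  r_uT <- x$r * 1e6
  term_T <- grid$T
  term_rf <- tau * pen$mu_rf / 2 * sum(r_uT^2)
  term_g <- tau * pen$mu_g / p * sum((st$Gs / problem$bounds$gmax)^p)
  e_out <- rep_len(pb$e_out, problem$space$nz)
  e_in <- rep_len(pb$e_in, problem$space$nz)
  out <- spec$out_slice
  ins <- spec$in_slice
  term_out <- delta * pen$mu_out / (2 * p) *
    sum((st$magnitude[out] / e_out[out])^p)
  term_in <- delta * pen$mu_in / (2 * p) *
    sum(((1 - st$magnitude[ins]) / e_in[ins])^p)
  st_ph <- slice_phase_stats(st$phase, spec)
  term_ph <- if (isFALSE(problem$phase_constrained)) 0 else
    delta * pen$mu_p / p * sum((st_ph$dev[ins] / pb$ep)^p)
  terms <- c(T = term_T, rf = term_rf, grad = term_g,
             out = term_out, in_slice = term_in, phase = term_ph)
  list(J = sum(terms), terms = terms, phase_stats = st_ph)
}

#' Penalized design cost with term breakdown
#'
#' Evaluates the full objective for fixed duration: the pulse duration plus
#' RF energy, demanded-gradient amplitude, out-of-slice, in-slice and
#' phase-spread Lp penalty terms.  The profile is computed through the
#' design GIRF.
#'
#' @param x a [control_vector()].
#' @param problem a [design_problem()].
#' @param pen a [penalty_state()].
#' @return List with `J`, the named 6-vector `terms`
#'   (`T, rf, grad, out, in_slice, phase`), the per-z constraint
#'   `violations` (magnitude and phase), `max_violation`, the simulated
#'   `magnitude`/`phase`, `Gs`, `Gt` and `sar`.
#' @export
design_cost <- function(x, problem, pen) {
  stopifnot(inherits(x, "control_vector"), inherits(problem, "design_problem"),
            inherits(pen, "penalty_state"))
  st <- forward_state(x, problem, pen)
  ct <- cost_terms(st, x, problem, pen)
  vm <- magnitude_violations(st$magnitude, problem$spec, problem$pbounds)
  vp <- phase_violations(st$phase, problem$spec, problem$pbounds)
  sar <- problem$sar$coil_eff * problem$sar$fp * x$grid$tau * sum((x$r * 1e6)^2)
  active <- if (problem$phase_constrained) c(vm, vp) else vm
  list(J = ct$J, terms = ct$terms,
       magnitude = st$magnitude, phase = st$phase,
       mag_violations = vm, phase_viol = vp,
       max_violation = max(active),
       Gs = st$Gs, Gt = st$Gt, sar = sar,
       mean_phase = attr(vp, "mean_phase"))
}

#' Adapt penalty weights from constraint activity
#'
#' Called every `adapt_every` (20) iterations of the lower-level solver:
#' each constraint group's weight doubles while its worst violation is
#' positive, relaxes by a factor 1.25 once the group is satisfied with a
#' margin of 10% of its bound, and is clamped to `[1e-6, 1e9]`.  If the
#' SAR estimate exceeds the configured limit, the RF energy weight doubles.
#'
#' @param pen a [penalty_state()].
#' @param cost a [design_cost()] result for the current iterate.
#' @param problem the [design_problem()].
#' @return The updated [penalty_state()].
#' @export
adapt_weights <- function(pen, cost, problem) {
  pb <- problem$pbounds
  spec <- problem$spec
  clamp <- function(w) min(max(w, 1e-6), 1e9)
  upd <- function(w, vmax, bound) {
    if (vmax > 0) w <- w * 2
    else if (vmax < -0.1 * bound) w <- w / 1.25
    clamp(w)
  }
  vout <- cost$mag_violations[spec$out_slice]
  vin <- cost$mag_violations[spec$in_slice]
  vph <- cost$phase_viol[spec$in_slice]
  pen$mu_out <- upd(pen$mu_out, max(vout), min(pb$e_out))
  pen$mu_in <- upd(pen$mu_in, max(vin), min(pb$e_in))
  if (problem$phase_constrained) pen$mu_p <- upd(pen$mu_p, max(vph), pb$ep)
  vg <- max(abs(cost$Gs)) - problem$bounds$gmax
  pen$mu_g <- upd(pen$mu_g, vg, problem$bounds$gmax)
  if (cost$sar > problem$sar$sar_max) pen$mu_rf <- clamp(pen$mu_rf * 2)
  pen$n_adapt <- pen$n_adapt + 1L
  pen
}

#' Double the Lp exponent (penalty continuation)
#'
#' `p <- min(2 * p, 32)`; raising `p` pushes the penalty terms toward the
#' maximum normalized violation (L-infinity-like behaviour).
#'
#' @param pen a [penalty_state()].
#' @param p_max saturation value.
#' @export
continue_p <- function(pen, p_max = 32L) {
  pen$p <- as.integer(min(2L * pen$p, p_max))
  pen
}
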