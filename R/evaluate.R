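#' Evaluate a design under an evaluation GIRF
#'
#' Filters the demanded gradient with `eval_girf`, simulates the
#' spin-domain profile, and reports the summary metrics: pulse duration,
#' maximal refocusing profile deviation `max_es` (largest absolute
#' deviation of `|b|^2` from its target -- 1 in-slice, 0 out-of-slice --
#' over the constrained domains), maximal in-slice phase deviation from
#' the slice mean `max_ep_rad`, the SAR estimate, and the signed
#' constraint violations against the problem's bounds.
#'
#' @param rf an [rf_waveform()].
#' @param grad a [gradient_waveform()] (the demanded waveform).
#' @param problem a [design_problem()] (its own `girf` is ignored here).
#' @param eval_girf a [transfer_function()], or `NULL` for the ideal
#'   response.
#' @return A list of class `design_metrics` with fields `T_ms`, `max_es`,
#'   `max_ep_rad`, `sar_w_per_kg`, `max_violation`, `magnitude`, `phase`.
#' @export
evaluate_design <- function(rf, grad, problem, eval_girf = NULL) {
  stopifnot(inherits(rf, "rf_waveform"), inherits(grad, "gradient_waveform"))
  grid <- rf$grid
  if (length(grad$Gs) != length(rf$r)) stop("rf and grad lengths differ")
  Gt <- if (is.null(eval_girf)) grad$Gs else apply_girf(grad, eval_girf)
  p <- simulate_spin_domain(rf, Gt, grid, problem$space)
  prof <- refocusing_profile(p)
  spec <- problem$spec
  dev_in <- abs(1 - prof$magnitude[spec$in_slice])
  dev_out <- abs(prof$magnitude[spec$out_slice])
  st_ph <- slice_phase_stats(prof$phase, spec)
  vm <- magnitude_violations(prof$magnitude, spec, problem$pbounds)
  vp <- phase_violations(prof$phase, spec, problem$pbounds)
  structure(list(
    T_ms = grid$T * 1e3,
    max_es = max(c(dev_in, dev_out)),
    max_ep_rad = max(abs(st_ph$dev[spec$in_slice])),
    sar_w_per_kg = sar_estimate(rf, grid, problem$sar),
    max_violation = if (problem$phase_constrained) max(c(vm, vp)) else max(vm),
    girf_label = if (is.null(eval_girf)) "Hi" else eval_girf$label,
    magnitude = prof$magnitude, phase = prof$phase, realized_grad = Gt),
    class = "design_metrics")
}

#' @export
print.design_metrics <- function(x, ...) {
  cat(sprintf("<design_metrics> eval %s: T = %.3f ms, max_es = %.4f, max_ep = %.4f rad, SARe = %.3f W/kg\n",
              x$girf_label, x$T_ms, x$max_es, x$max_ep_rad, x$sar_w_per_kg))
  invisible(x)
}

#' Cross-evaluation of designs against a set of GIRFs
#'
#' Evaluates every design under every evaluation GIRF and tabulates the
#' summary metrics, to analyze the influence of designing for one
#' gradient axis and playing the pulse on another.
#'
#' @param designs named list; each element has components `rf` and `grad`
#'   (e.g. [build_pins()] or [solve_time_optimal()] results).
#' @param girfs named list of [transfer_function()] (use `NULL` entries
#'   for the ideal response).
#' @param problem a [design_problem()].
#' @return A data.frame with one row per (design, evaluation) pair.
#' @export
cross_girf_matrix <- function(designs, girfs, problem) {
  rows <- list()
  for (dn in names(designs)) {
    for (gn in names(girfs)) {
      m <- evaluate_design(designs[[dn]]$rf, designs[[dn]]$grad,
                           problem, girfs[[gn]])
      rows[[length(rows) + 1L]] <- data.frame(
        design = dn, eval_girf = gn, T_ms = m$T_ms, max_es = m$max_es,
        max_ep_rad = m$max_ep_rad, sar_w_per_kg = m$sar_w_per_kg,
        max_violation = m$max_violation)
    }
  }
  do.call(rbind, rows)
}

#' Sweep design parameters
#'
#' Builds (and optionally optimizes) one design per row of a parameter
#' grid, recording initial and final durations and evaluation metrics.
#' Cell failures are caught and recorded; the sweep continues.
#'
#' @param cells data.frame with columns `mb`, `tbwp`, `thk_m`, `fov_m`.
#' @param problem_fun function(mb, tbwp, thk_m, fov_m) returning the
#'   [design_problem()] for a cell (lets the caller pick spatial grids and
#'   bounds appropriate to each FOV).
#' @param bounds a [hardware_bounds()].
#' @param tau raster time (s).
#' @param optimize run [solve_time_optimal()] per cell (otherwise only the
#'   PINS initialization is reported).
#' @param config a [solver_config()] for optimized sweeps.
#' @return `cells` augmented with `T_init_ms`, `T_opt_ms`, `max_es`,
#'   `sar_w_per_kg`, `ok`, `error`.
#' @export
parameter_sweep <- function(cells, problem_fun, bounds = hardware_bounds(),
                            tau = 6.4e-6, optimize = FALSE,
                            config = solver_config()) {
  out <- cells
  out$T_init_ms <- NA_real_
  out$T_opt_ms <- NA_real_
  out$max_es <- NA_real_
  out$sar_w_per_kg <- NA_real_
  out$ok <- FALSE
  out$error <- NA_character_
  for (i in seq_len(nrow(cells))) {
    res <- tryCatch({
      ce <- cells[i, ]
      pins <- build_pins(ce$mb, ce$tbwp, ce$thk_m, ce$fov_m, bounds, tau)
      problem <- problem_fun(ce$mb, ce$tbwp, ce$thk_m, ce$fov_m)
      out$T_init_ms[i] <- pins$duration_ms
      if (optimize) {
        des <- solve_time_optimal(problem, pins_controls(pins),
                                  config = config)
        m <- evaluate_design(des$rf, des$grad, problem, problem$girf)
        out$T_opt_ms[i] <- des$duration_ms
      } else {
        m <- evaluate_design(pins$rf, pins$grad, problem, problem$girf)
      }
      out$max_es[i] <- m$max_es
      out$sar_w_per_kg[i] <- m$sar_w_per_kg
      out$ok[i] <- TRUE
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) out$error[i] <- res
  }
  out
}

#' Minimal-time trapezoidal ramp-down of the terminal gradient value
#'
#' The optimized window ends wherever the optimizer left the demanded
#' gradient; sequence integration needs a ramp back to zero.  This helper
#' returns the minimum-time linear ramp (informational; it is not part of
#' the optimized waveform and not simulated).
#'
#' @param g_end terminal gradient value (T/m).
#' @param bounds a [hardware_bounds()].
#' @param tau raster time (s).
#' @return Numeric vector of gradient samples ending at 0 (possibly empty).
#' @export
ramp_down <- function(g_end, bounds, tau) {
  n <- ceiling(abs(g_end) / (bounds$smax * tau))
  if (n == 0) return(numeric(0))
  g_end * (n - seq_len(n)) / n
}
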