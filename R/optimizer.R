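# Lower-level solver (projected limited-memory quasi-Newton with penalty
# adaptation and p-continuation) and the bilevel minimum-duration search.

#' Solver configuration
#'
#' @param lbfgs_memory number of curvature pairs kept.
#' @param max_iter iteration cap of one fixed-duration solve.
#' @param ls_max maximal backtracking halvings per line search.
#' @param shrink_rho outer-loop duration shrink factor per accepted step.
#' @param p_max saturation exponent of the Lp continuation.
#' @param adapt_every penalty weights adapt after every this many steps.
#' @param tol_violation feasibility tolerance on the signed constraint
#'   violations (absolute, in the units of each bound).
#' @param tol_decrease relative cost decrease below which a feasible
#'   iterate terminates the solve.
#' @param stagnation_window,stagnation_tol trigger for p-continuation:
#'   relative decrease below `stagnation_tol` over this many iterations.
#' @param p_raise_viol raise the exponent only while the worst violation is
#'   below this level; raising p far from feasibility makes the penalty
#'   terms astronomically ill-conditioned.
#' @param max_solves total budget of lower-level solves across the bilevel
#'   search (initial solve included).
#' @param verbose print per-iteration progress.
#' @export
solver_config <- function(lbfgs_memory = 20L, max_iter = 400L, ls_max = 25L,
                          shrink_rho = 0.9, p_max = 32L, adapt_every = 20L,
                          tol_violation = 1e-3, tol_decrease = 1e-6,
                          stagnation_window = 10L, stagnation_tol = 1e-5,
                          p_raise_viol = 0.01, max_solves = 40L,
                          verbose = FALSE) {
  structure(list(lbfgs_memory = as.integer(lbfgs_memory),
                 max_iter = as.integer(max_iter), ls_max = as.integer(ls_max),
                 shrink_rho = shrink_rho, p_max = as.integer(p_max),
                 adapt_every = as.integer(adapt_every),
                 tol_violation = tol_violation, tol_decrease = tol_decrease,
                 stagnation_window = as.integer(stagnation_window),
                 stagnation_tol = stagnation_tol,
                 p_raise_viol = p_raise_viol,
                 max_solves = as.integer(max_solves),
                 verbose = isTRUE(verbose)),
            class = "solver_config")
}

# -- packing between control_vector and the scaled optimization vector ----
# Real-valued mode optimizes the signed amplitude u = r*cos(theta) in
# [-rmax, rmax]; complex mode optimizes (r, theta) directly.  Everything is
# scaled by its bound so the box is [-1, 1]^d (theta by pi).
pack_controls <- function(x, bounds) {
  if (x$real_valued) {
    c(x$r * cos(x$theta) / bounds$rmax, x$s / bounds$smax)
  } else {
    c(x$r / bounds$rmax, x$theta / pi, x$s / bounds$smax)
  }
}

unpack_controls <- function(v, grid, bounds, real_valued) {
  n <- n_intervals(grid)
  if (real_valued) {
    u <- v[seq_len(n)] * bounds$rmax
    s <- v[n + seq_len(n)] * bounds$smax
    control_vector(abs(u), ifelse(u >= 0, 0, pi), s, grid, real_valued = TRUE)
  } else {
    control_vector(v[seq_len(n)] * bounds$rmax, v[n + seq_len(n)] * pi,
                   v[2 * n + seq_len(n)] * bounds$smax, grid,
                   real_valued = FALSE)
  }
}

pack_gradient <- function(gr, x, bounds) {
  if (x$real_valued) {
    c(gr$d_b1_re * bounds$rmax, gr$d_s * bounds$smax)
  } else {
    c(gr$d_r * bounds$rmax, gr$d_theta * pi, gr$d_s * bounds$smax)
  }
}

box_limits <- function(n, real_valued) {
  d <- if (real_valued) 2L * n else 3L * n
  lo <- rep(-1, d)
  hi <- rep(1, d)
  if (!real_valued) lo[seq_len(n)] <- 0   # r >= 0
  list(lo = lo, hi = hi)
}

project_box <- function(v, box) pmin(pmax(v, box$lo), box$hi)

# two-loop L-BFGS recursion
lbfgs_direction <- function(g, mem) {
  q <- g
  k <- length(mem$s)
  if (k == 0L) return(-g)
  al <- numeric(k)
  for (i in k:1) {
    al[i] <- mem$rho[[i]] * sum(mem$s[[i]] * q)
    q <- q - al[i] * mem$y[[i]]
  }
  gam <- sum(mem$s[[k]] * mem$y[[k]]) / sum(mem$y[[k]] * mem$y[[k]])
  q <- gam * q
  for (i in 1:k) {
    be <- mem$rho[[i]] * sum(mem$y[[i]] * q)
    q <- q + (al[i] - be) * mem$s[[i]]
  }
  -q
}

#' Solve the design problem at fixed pulse duration
#'
#' Projected limited-memory BFGS descent on the penalized cost with
#' backtracking line search; hardware box bounds on the controls are
#' enforced by projection at every candidate point.  Penalty weights adapt
#' every `adapt_every` iterations; when progress stalls the Lp exponent is
#' doubled (continuation) until `p_max`.  Terminates when the iterate is
#' feasible (all signed violations below `tol_violation`) and the relative
#' cost decrease falls below `tol_decrease`, or at the iteration cap.
#'
#' @param problem a [design_problem()].
#' @param x0 initial [control_vector()] (projected onto the bounds).
#' @param pen0 initial [penalty_state()].
#' @param config a [solver_config()].
#' @return List with the solution `x`, its [design_cost()] `cost`, the
#'   final `pen`, and a `report` (iterations, J history, p schedule,
#'   weight history, convergence flag).
#' @export
solve_fixed_t <- function(problem, x0, pen0 = penalty_state(),
                          config = solver_config()) {
  bounds <- problem$bounds
  grid <- x0$grid
  n <- n_intervals(grid)
  x0 <- project_controls(x0, bounds)
  box <- box_limits(n, x0$real_valued)
  v <- project_box(pack_controls(x0, bounds), box)
  pen <- pen0
  evalJ <- function(v) {
    design_cost(unpack_controls(v, grid, bounds, x0$real_valued), problem, pen)
  }
  evalG <- function(v) {
    x <- unpack_controls(v, grid, bounds, x0$real_valued)
    gr <- cost_gradient(x, problem, pen)
    list(x = x, gr = gr, g = pack_gradient(gr, x, bounds))
  }
  cur <- evalJ(v)
  mem <- list(s = list(), y = list(), rho = list())
  g_prev <- NULL
  v_prev <- NULL
  J_hist <- cur$J
  p_hist <- pen$p
  w_hist <- list(unlist(pen[c("mu_rf", "mu_g", "mu_out", "mu_in", "mu_p")]))
  converged <- FALSE
  best <- list(v = v, cost = cur)
  fail_count <- 0L
  it <- 0L
  while (it < config$max_iter) {
    it <- it + 1L
    ev <- evalG(v)
    g <- ev$g
    if (any(!is.finite(g))) stop("non-finite gradient at iteration ", it)
    if (!is.null(g_prev)) {
      sv <- v - v_prev
      yv <- g - g_prev
      sy <- sum(sv * yv)
      if (is.finite(sy) && sy > 1e-12 * sqrt(sum(sv^2) * sum(yv^2))) {
        mem$s <- c(mem$s, list(sv))
        mem$y <- c(mem$y, list(yv))
        mem$rho <- c(mem$rho, list(1 / sy))
        if (length(mem$s) > config$lbfgs_memory) {
          mem$s <- mem$s[-1L]; mem$y <- mem$y[-1L]; mem$rho <- mem$rho[-1L]
        }
      }
    }
    d <- lbfgs_direction(g, mem)
    # trust-region-style safeguard: never propose more than a quarter of
    # the unit control box in one step
    dmax <- max(abs(d))
    if (dmax > 0.25) d <- d * (0.25 / dmax)
    v_prev <- v
    g_prev <- g
    # projected backtracking line search
    alpha <- 1
    ok <- FALSE
    for (ls in seq_len(config$ls_max)) {
      v_try <- project_box(v + alpha * d, box)
      step <- v_try - v
      if (max(abs(step)) < 1e-15) break
      c_try <- evalJ(v_try)
      if (is.finite(c_try$J) &&
          c_try$J <= cur$J + 1e-4 * sum(g * step)) {
        ok <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!ok) {
      # retry as normalized steepest descent with fresh memory; step scaled
      # to the unit box the controls live in
      mem <- list(s = list(), y = list(), rho = list())
      d <- -g / max(sqrt(sum(g^2)), 1e-30)
      alpha <- 0.1
      for (ls in seq_len(config$ls_max)) {
        v_try <- project_box(v + alpha * d, box)
        step <- v_try - v
        if (max(abs(step)) < 1e-15) break
        c_try <- evalJ(v_try)
        if (is.finite(c_try$J) && c_try$J < cur$J) {
          ok <- TRUE
          break
        }
        alpha <- alpha / 2
      }
    }
    if (!ok) {
      # projected stationary point for the current penalty: sharpen the
      # penalty (adapt weights, raise p) and try again a few times
      fail_count <- fail_count + 1L
      if (fail_count > 4L ||
          (cur$max_violation <= config$tol_violation &&
           pen$p >= config$p_max)) break
      pen <- adapt_weights(pen, cur, problem)
      if (pen$p < config$p_max &&
          cur$max_violation <= config$p_raise_viol) {
        pen <- continue_p(pen, config$p_max)
        p_hist <- c(p_hist, pen$p)
      }
      w_hist <- c(w_hist, list(unlist(pen[c("mu_rf", "mu_g", "mu_out",
                                            "mu_in", "mu_p")])))
      mem <- list(s = list(), y = list(), rho = list())
      g_prev <- NULL
      cur <- evalJ(v)
      J_hist <- c(J_hist, cur$J)
      next
    }
    fail_count <- 0L
    v <- v_try
    cur <- c_try
    J_hist <- c(J_hist, cur$J)
    if (cur$max_violation <= best$cost$max_violation ||
        (cur$max_violation <= config$tol_violation && cur$J < best$cost$J))
      best <- list(v = v, cost = cur)
    if (config$verbose && it %% 10L == 0L)
      message(sprintf("  it %4d  J = %.6g  max viol = %.3g  p = %d",
                      it, cur$J, cur$max_violation, pen$p))
    # convergence: feasible and stalled
    nh <- length(J_hist)
    rel_dec <- if (nh >= 2L)
      (J_hist[nh - 1L] - J_hist[nh]) / max(abs(J_hist[nh - 1L]), 1e-30)
    else Inf
    if (cur$max_violation <= config$tol_violation &&
        rel_dec < config$tol_decrease && pen$p >= config$p_max) {
      converged <- TRUE
      break
    }
    # penalty adaptation; the x2 weight steps perturb the objective gently
    # enough that the curvature memory stays useful
    if (it %% config$adapt_every == 0L) {
      pen <- adapt_weights(pen, cur, problem)
      w_hist <- c(w_hist, list(unlist(pen[c("mu_rf", "mu_g", "mu_out",
                                            "mu_in", "mu_p")])))
      g_prev <- NULL
      cur <- evalJ(v)
      J_hist <- c(J_hist, cur$J)
    }
    # p-continuation on stagnation
    wdw <- config$stagnation_window
    if (length(J_hist) > wdw) {
      span <- (J_hist[nh - wdw + 1L] - J_hist[nh]) /
        max(abs(J_hist[nh - wdw + 1L]), 1e-30)
      if (span < config$stagnation_tol && pen$p < config$p_max &&
          cur$max_violation <= config$p_raise_viol) {
        pen <- continue_p(pen, config$p_max)
        p_hist <- c(p_hist, pen$p)
        mem <- list(s = list(), y = list(), rho = list())
        g_prev <- NULL
        cur <- evalJ(v)
        J_hist <- c(J_hist, cur$J)
      }
    }
  }
  # return the best feasible-leaning iterate
  x_out <- unpack_controls(best$v, grid, bounds, x0$real_valued)
  pen_out <- pen
  report <- list(iterations = it, J = best$cost$J, terms = best$cost$terms,
                 max_violation = best$cost$max_violation,
                 J_history = J_hist, p_schedule = p_hist,
                 weight_history = w_hist, converged = converged)
  list(x = x_out, cost = best$cost, pen = pen_out, report = report)
}

#' Bilevel minimum-duration design
#'
#' Upper level of the time-optimal search: starting from a feasible
#' initialization (typically the PINS pulse), solve at the initial
#' duration, then repeatedly shrink the grid by `shrink_rho` (resampling
#' the incumbent controls) and re-solve while the result stays feasible;
#' on the first infeasible duration, bisect the interval count between the
#' last feasible and first infeasible grid down to a single raster sample.
#'
#' @param problem a [design_problem()].
#' @param x0 initial [control_vector()] (e.g. from [pins_controls()]).
#' @param pen0 initial [penalty_state()].
#' @param config a [solver_config()].
#' @return A list of class `design_result`: optimized `rf`, `grad`,
#'   `grid`, `x`, final `cost`, `duration_ms`, the accepted duration
#'   sequence `T_accepted_ms`, and per-solve `reports`.
#' @export
solve_time_optimal <- function(problem, x0, pen0 = penalty_state(),
                               config = solver_config()) {
  stopifnot(inherits(x0, "control_vector"))
  tau <- x0$grid$tau
  feasible <- function(sol) sol$cost$max_violation <= config$tol_violation
  solve_at <- function(nt, x_warm) {
    grid <- time_grid(tau, nt)
    x_init <- resample_controls(x_warm, grid, problem$bounds,
                                preserve = "moment")
    solve_fixed_t(problem, x_init, pen0, config)
  }
  sol <- solve_fixed_t(problem, project_controls(x0, problem$bounds),
                       pen0, config)
  if (!feasible(sol))
    stop("initialization is infeasible at its own duration (max violation ",
         signif(sol$cost$max_violation, 3),
         "); fix the initializer or relax the bounds")
  accepted <- sol
  T_acc <- accepted$x$grid$T
  reports <- list(accepted$report)
  nt_good <- accepted$x$grid$nt
  # Shrink-then-bisect, iterated: a failed duration is not proof of
  # infeasibility (the lower-level solve is local and budgeted), so once a
  # bisection collapses the search restarts from the new incumbent -- its
  # warm start is better than the one the failed leg saw -- and stops when
  # a whole cycle brings no improvement.
  n_solves <- 1L
  repeat {
    nt_cycle_start <- nt_good
    nt_low <- NULL                     # first infeasible nt of this cycle
    while (n_solves < config$max_solves) {
      nt_try <- if (is.null(nt_low)) {
        max(2L, as.integer(floor(config$shrink_rho * (nt_good - 1L))) + 1L)
      } else {
        as.integer(floor((nt_good + nt_low) / 2))
      }
      if (nt_try >= nt_good) break
      if (!is.null(nt_low) && nt_good - nt_low <= 1L) break
      cand <- solve_at(nt_try, accepted$x)
      n_solves <- n_solves + 1L
      reports <- c(reports, list(cand$report))
      if (feasible(cand)) {
        accepted <- cand
        nt_good <- nt_try
        T_acc <- c(T_acc, cand$x$grid$T)
      } else {
        nt_low <- nt_try
        if (nt_good - nt_low <= 1L) break
      }
    }
    if (nt_good >= nt_cycle_start - 1L || n_solves >= config$max_solves)
      break
  }
  x <- accepted$x
  rf <- rf_waveform(x$r, x$theta, x$grid, real_valued = x$real_valued)
  grad <- integrate_slew(x$s, x$grid)
  structure(list(rf = rf, grad = grad, grid = x$grid, x = x,
                 cost = accepted$cost, pen = accepted$pen,
                 duration_ms = x$grid$T * 1e3,
                 T_accepted_ms = T_acc * 1e3,
                 reports = reports, problem = problem),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("<design_result> T = %.3f ms, max violation = %.3g, SARe = %.3f W/kg\n",
              x$duration_ms, x$cost$max_violation, x$cost$sar))
  cat(sprintf("  accepted durations (ms): %s\n",
              paste(sprintf("%.3f", x$T_accepted_ms), collapse = " -> ")))
  invisible(x)
}

#' Controls of a PINS pulse
#'
#' Convenience conversion of a [build_pins()] result into the
#' [control_vector()] that initializes the optimizer.
#'
#' @param pins a `pins_pulse`.
#' @export
pins_controls <- function(pins) {
  stopifnot(inherits(pins, "pins_pulse"))
  s <- pins$grad$s
  control_vector(pins$rf$r, pins$rf$theta, s, pins$grid,
                 real_valued = pins$rf$real_valued)
}
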