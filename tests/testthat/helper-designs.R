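# Shared, lazily computed optimization results (expensive fixtures).
.design_cache <- new.env(parent = emptyenv())

# Small single-slice minimum-duration design used by the solver property
# tests: MB = 1, THK = 6 mm, FOV = 30 mm, coarse raster.
toy_time_optimal <- function() {
  if (!is.null(.design_cache$toy)) return(.design_cache$toy)
  hb <- hardware_bounds()
  tau <- 25.6e-6
  pins <- build_pins(1, 2, 6e-3, 30e-3, hb, tau)
  space <- spatial_grid(30e-3, 49)
  spec <- build_slice_domains(1, 6e-3, 30e-3, 2, space, ftw = 0.4)
  problem <- design_problem(spec, hb, profile_bounds(0.02, 0.05))
  cfg <- solver_config(max_iter = 120, shrink_rho = 0.7)
  des <- solve_time_optimal(problem, pins_controls(pins), penalty_state(),
                            cfg)
  .design_cache$toy <- list(pins = pins, problem = problem, des = des,
                            cfg = cfg)
  .design_cache$toy
}

# Desk-scale two-slice designs demonstrating GIRF pre-emphasis: designed
# with and without a synthetic low-pass GIRF (3.75 kHz, 50 us delay),
# MB = 2, FOV = 60 mm, 256 spatial points, 12.8 us raster, es = 2%.
desk_scale_designs <- function() {
  if (!is.null(.design_cache$desk)) return(.design_cache$desk)
  hb <- hardware_bounds()
  tau <- 12.8e-6
  pins <- build_pins(2, 3, 5e-3, 60e-3, hb, tau)
  space <- spatial_grid(60e-3, 256)
  spec <- build_slice_domains(2, 5e-3, 60e-3, 3, space)
  girf <- synthetic_girf(3750, delay_s = 50e-6)
  cfg <- solver_config(max_iter = 400, shrink_rho = 0.8, max_solves = 14)
  out <- list(pins = pins, tf = girf)
  for (nm in c("hi", "girf")) {
    problem <- design_problem(spec, hb, profile_bounds(0.02, 0.025),
                              girf = if (nm == "hi") NULL else girf)
    out[[nm]] <- list(problem = problem,
                      des = solve_time_optimal(problem, pins_controls(pins),
                                               penalty_state(), cfg))
  }
  .design_cache$desk <- out
  out
}
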