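# The experiment grid: stroke optimization per joint-range preset and
# active-limb set, and the slim-versus-bulky body comparison.

# box bounds over the flat 26-vector for a given preset; single-pair
# experiments search only the active 13 coordinates
stroke_bounds <- function(preset, period = 1 / STROKE_FREQUENCY) {
  limb <- function(b) {
    lo <- c(b$dv[1], b$dv[1], 0, b$ap[1], b$ap[1], 0, b$rot[1], b$rot[1], 0,
            0.05, 0.05, 0.05, 0)
    hi <- c(b$dv[2], b$dv[2], 1, b$ap[2], b$ap[2], 1, b$rot[2], b$rot[2], 1,
            0.95, 0.95, 0.95, 0.95 * period)
    list(lo = lo, hi = hi)
  }
  f <- limb(preset$fore); h <- limb(preset$hind)
  list(lower = c(f$lo, h$lo), upper = c(f$hi, h$hi))
}

# initial mean: mid-amplitude stroke (extreme coordinates at the box
# quartiles), dv leading and ap/rot lagging by a quarter period, symmetric
# timing, no rotation hold
stroke_initial_mean <- function(preset, period = 1 / STROKE_FREQUENCY) {
  limb <- function(b) {
    q <- function(bd, f) bd[1] + f * (bd[2] - bd[1])
    c(q(b$dv, 0.25), q(b$dv, 0.75), 0.0,
      q(b$ap, 0.25), q(b$ap, 0.75), 0.25,
      q(b$rot, 0.25), q(b$rot, 0.75), 0.25,
      0.5, 0.5, 0.5, 0)
  }
  c(limb(preset$fore), limb(preset$hind))
}

# embed an active-limb search vector into the full 26-vector
embed_stroke_vector <- function(v_active, active_limbs, preset) {
  full <- stroke_initial_mean(preset)
  freeze <- function(block, lb) {
    nn <- preset$neutral[[lb]]
    # zero-amplitude sinusoids at the neutral pose
    c(nn[["dv"]], nn[["dv"]], 0, nn[["ap"]], nn[["ap"]], 0,
      nn[["rot"]], nn[["rot"]], 0, 0.5, 0.5, 0.5, 0)
  }
  if (active_limbs == "all") {
    stopifnot(length(v_active) == 26)
    return(v_active)
  }
  if (active_limbs == "fore") {
    stopifnot(length(v_active) == 13)
    return(c(v_active, freeze(14:26, "hind")))
  }
  stopifnot(length(v_active) == 13)
  c(freeze(1:13, "fore"), v_active)
}

# dimensions of the search space per active-limb set
search_dim <- function(active_limbs) if (active_limbs == "all") 26L else 13L

#' Optimize a swimming stroke for one experiment condition
#'
#' Runs CMA-ES over the stroke space of the active limb pairs (26
#' dimensions for all limbs, 13 for a single pair: nine sinusoid values,
#' three asymmetries and one rotation hold), evaluating each sample with a
#' full coupled simulation and the straight-swimming quality over the
#' second stroke cycle.  The best sample is re-simulated and its full
#' trajectory archived.
#'
#' @param preset Preset name ("narrow", "medium", "wide") or a
#'   [joint_presets()] object.
#' @param active_limbs "all", "fore" or "hind".
#' @param body A `psw_body`; default is the slim swimmer.
#' @param config A [sim_config()]; defaults to the coarse grid for cost.
#' @param popsize,maxiter,seed,workers CMA-ES controls (the full-scale
#'   reference settings are 31 samples and about 70 iterations).
#' @param w_dir,w_orient Quality penalty weights.
#' @return List with the `psw_optrun`, the best decoded
#'   [stroke_params()], the re-simulated best `trajectory` and its
#'   [quality()].
#' @export
run_experiment <- function(preset = "medium", active_limbs = "all",
                           body = NULL, config = sim_config("coarse"),
                           popsize = 8, maxiter = 20, seed = 1,
                           workers = 1, w_dir = 1, w_orient = 0.5) {
  if (is.character(preset)) preset <- joint_presets(preset)
  # the fluid grid cannot resolve features thinner than one cell: the
  # procedural body is generated with its thin features held at or above
  # the active cell size (the reference model's 67 mm floor scaled to dx)
  if (is.null(body))
    body <- build_swimmer(body_spec(min_thickness = max(0.067,
                                                        config$grid$dx)))
  model <- dynamics_model(body)
  bounds <- stroke_bounds(preset)
  dims <- if (active_limbs == "all") 1:26 else
    if (active_limbs == "fore") 1:13 else 14:26
  objective <- function(v) {
    full <- embed_stroke_vector(v, active_limbs, preset)
    stroke <- decode_stroke(full, preset, warn = FALSE)
    traj <- try(run_simulation(body, stroke, preset, active_limbs, config,
                               model = model), silent = TRUE)
    if (inherits(traj, "try-error")) return(NA_real_)
    quality(traj, w_dir, w_orient)$quality
  }
  run <- cma_optimize(objective,
                      lower = bounds$lower[dims], upper = bounds$upper[dims],
                      x0 = stroke_initial_mean(preset)[dims],
                      popsize = popsize, maxiter = maxiter, seed = seed,
                      workers = workers)
  best_full <- embed_stroke_vector(run$best_par, active_limbs, preset)
  best_stroke <- decode_stroke(best_full, preset, warn = FALSE)
  traj <- run_simulation(body, best_stroke, preset, active_limbs, config,
                         model = model)
  list(run = run, stroke = best_stroke, stroke_vector = best_full,
       trajectory = traj, quality = quality(traj, w_dir, w_orient),
       preset = preset$name, active_limbs = active_limbs)
}

#' Re-run fixed strokes on slim and bulky body variants
#'
#' Takes stroke vectors obtained on the slim model and re-simulates them
#' unchanged on the muscle-bulk variant (no re-optimization), reporting
#' swimming distance and vertical deviation per condition.
#'
#' @param strokes Named list of 26-vectors (e.g. from [run_experiment()]),
#'   names giving the active-limb set ("all", "fore", "hind").
#' @param preset Preset name or [joint_presets()].
#' @param config A [sim_config()].
#' @param bulk_factor Muscle-bulk factor of the modified body.
#' @return Data frame with one row per condition and body variant:
#'   distance (m) and vertical deviation (m) over the quality cycle.
#' @export
compare_body_variants <- function(strokes, preset = "medium",
                                  config = sim_config("coarse"),
                                  bulk_factor = 1.5) {
  if (is.character(preset)) preset <- joint_presets(preset)
  mt <- max(0.067, config$grid$dx)
  slim <- build_swimmer(body_spec(min_thickness = mt))
  bulk <- build_swimmer(body_spec(min_thickness = mt,
                                  muscle_bulk_factor = bulk_factor))
  rows <- list()
  for (nm in names(strokes)) {
    stroke <- decode_stroke(strokes[[nm]], preset, warn = FALSE)
    for (variant in c("slim", "bulk")) {
      body <- if (variant == "slim") slim else bulk
      traj <- run_simulation(body, stroke, preset, nm, config)
      qq <- quality(traj)
      rows[[length(rows) + 1]] <- data.frame(
        limbs = nm, body = variant,
        distance = qq$forward_distance,
        vertical_deviation = abs(qq$vertical_deviation),
        speed = qq$mean_speed)
    }
  }
  do.call(rbind, rows)
}

#' Quasi-steady drag-paddle surrogate objective
#'
#' A fast closed-form swimmer used to exercise the optimizer without the
#' fluid solver: the body accelerates against quadratic drag, each limb
#' produces quasi-steady thrust from its dorsoventral blade speed with the
#' blade feathered by the rotation DOF, and quality is the distance
#' covered in the second cycle minus the straightness penalty implied by
#' net unbalanced vertical force.  The mapping from the 26-vector is the
#' same encode/decode path as the full simulator.
#'
#' @param preset A [joint_presets()] (or name).
#' @param active_limbs "all", "fore" or "hind".
#' @return Function mapping a search vector (26 or 13 values) to quality.
#' @export
paddle_objective <- function(preset = "medium", active_limbs = "all") {
  if (is.character(preset)) preset <- joint_presets(preset)
  mb <- 274          # body mass, kg
  kb <- 60           # quadratic body drag, N s^2/m^2
  kp <- 120          # paddle force coefficient, N s^2/m^2
  r_eff <- 0.5       # effective blade radius, m
  dt <- 0.01
  period <- 1 / STROKE_FREQUENCY
  function(v) {
    full <- embed_stroke_vector(v, active_limbs, preset)
    stroke <- decode_stroke(full, preset, warn = FALSE)
    pairs <- list(fore = stroke$fore, hind = stroke$hind)
    act <- if (active_limbs == "all") c("fore", "hind") else active_limbs
    vel <- 0
    dist1 <- 0
    dist2 <- 0
    vert <- 0
    tgrid <- seq(0, 2 * period, by = dt)
    for (t in tgrid[-1]) {
      thrust <- 0
      lift <- 0
      for (lb in act) {
        ls <- pairs[[lb]]
        th <- deg2rad(eval_dof(ls$dv, 0, t, period))
        thp <- deg2rad(eval_dof(ls$dv, 0, t + 1e-4, period) -
                       eval_dof(ls$dv, 0, t - 1e-4, period)) / 2e-4
        gam <- deg2rad(eval_dof(ls$rot, ls$hold, t, period))
        hdot <- r_eff * thp * cos(th)          # vertical blade speed
        sp2 <- vel^2 + hdot^2
        alpha <- atan2(-hdot, max(vel, 0.05)) - gam
        cl <- sin(2 * alpha)
        # two limbs per pair, lift decomposed along travel and vertical
        thrust <- thrust + 2 * kp * sp2 * cl * (-hdot) / sqrt(sp2 + 1e-9)
        lift <- lift + 2 * kp * sp2 * cl * vel / sqrt(sp2 + 1e-9)
      }
      acc <- (thrust - kb * vel * abs(vel)) / mb
      vel <- max(0, vel + dt * acc)
      vert <- vert + dt * lift / mb
      if (t <= period) dist1 <- dist1 + vel * dt else dist2 <- dist2 + vel * dt
    }
    dist2 - 0.1 * abs(vert)
  }
}
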