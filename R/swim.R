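# Swimming-simulation orchestration and the straight-swimming quality
# function.
#
# A simulation starts from rest (still water, static body) with the active
# limbs fully abducted and the inactive limbs locked at neutral, runs the
# coupled stepper for a whole number of stroke cycles, and records the
# body trajectory at every control tick.  Quality is evaluated over the
# second cycle only: the first cycle is the start-up transient.

#' Simulation configuration
#'
#' @param grid_scale "paper" (100x80x60), "desk" (50x40x30), "coarse"
#'   (25x20x15) or "mini" (20x16x12), all over the same
#'   6.6 x 5.28 x 3.96 m^3 domain.
#' @param dt Control/fluid time step in seconds.
#' @param n_cycles Number of stroke cycles to simulate (>= 2 so the
#'   quality window exists).
#' @param subres Voxelization sub-grid resolution.
#' @param start Body COM start position; the default places the swimmer
#'   with room to travel forward and well below the free surface.
#' @param gravity Gravity treatment, see [coupled_step()].
#' @param rtol Pressure-solve relative tolerance per step.
#' @param scheme Advection scheme.
#' @param snapshot_every Save a velocity-field snapshot every this many
#'   steps (0 = never); snapshots enable [particle_traces()].
#' @return A `psw_sim_config` list.
#' @export
sim_config <- function(grid_scale = "desk", dt = 0.02, n_cycles = 2,
                       subres = 3, start = c(2.4, 0, 1.85),
                       gravity = "balanced", rtol = 1e-7, scheme = "bfecc",
                       snapshot_every = 0) {
  grid <- if (inherits(grid_scale, "psw_grid")) grid_scale else {
    if (grid_scale == "mini") make_grid(c(20, 16, 12)) else
      grid_scale(match.arg(grid_scale, c("paper", "desk", "coarse")))
  }
  structure(list(grid = grid, dt = dt, n_cycles = n_cycles, subres = subres,
                 start = start, gravity = gravity, rtol = rtol,
                 scheme = scheme, snapshot_every = snapshot_every),
            class = "psw_sim_config")
}

#' Run a full coupled swimming simulation
#'
#' @param body A [build_swimmer()] result (or any `psw_body`).
#' @param stroke A [stroke_params()].
#' @param preset A [joint_presets()] (neutral/abducted poses and bounds).
#' @param active_limbs "all", "fore" or "hind"; inactive pairs are locked
#'   at the neutral pose and the active pairs start fully abducted.
#' @param config A [sim_config()].
#' @param model Optional pre-built [dynamics_model()] for `body`.
#' @param start_pose_deg Optional anatomical 12-vector (degrees) overriding
#'   the default start pose (active limbs fully abducted, inactive at
#'   neutral); e.g. pass the stroke's own pose at t = 0 to start without a
#'   transient swing.
#' @return A `psw_trajectory`: data frame `track` (time, COM position,
#'   heading, joint angles), the final state, and run metadata.
#' @export
run_simulation <- function(body, stroke, preset = joint_presets("medium"),
                           active_limbs = "all", config = sim_config(),
                           model = NULL, start_pose_deg = NULL) {
  if (is.null(model)) model <- dynamics_model(body)
  period <- 1 / stroke$frequency
  dt <- config$dt
  nsteps <- round(config$n_cycles * period / dt)
  fl <- mac_state(config$grid)
  # start pose: active limbs fully abducted, inactive at neutral
  pose0 <- if (is.null(start_pose_deg)) start_pose(preset, active_limbs)
           else start_pose_deg
  st <- init_state(x = config$start,
                   qj = anatomical_to_frame(model, pose0))
  targets <- function(t) joint_targets(stroke, t, active_limbs, preset)
  nrec <- nsteps + 1
  track <- data.frame(t = numeric(nrec), x = numeric(nrec), y = numeric(nrec),
                      z = numeric(nrec), bx = numeric(nrec),
                      by = numeric(nrec), bz = numeric(nrec))
  rotm <- matrix(0, nrec, 9)
  qjm <- matrix(0, nrec, length(st$qj))
  taum <- matrix(0, nrec, length(st$qj))
  record <- function(i, st, tau) {
    com <- body_momentum(model, st)$com
    track[i, ] <<- c(st$t, com, st$x)
    rotm[i, ] <<- as.vector(st$Rb)
    qjm[i, ] <<- st$qj
    if (!is.null(tau) && length(tau) >= 6) taum[i, ] <<- tau[-(1:6)]
  }
  record(1, st, NULL)
  snaps <- list()
  for (i in seq_len(nsteps)) {
    res <- coupled_step(fl, model, st, targets, dt, subres = config$subres,
                        gravity = config$gravity, scheme = config$scheme,
                        rtol = config$rtol)
    fl <- res$fluid
    st <- res$state
    record(i + 1, st, res$tau)
    if (config$snapshot_every > 0 && i %% config$snapshot_every == 0)
      snaps[[length(snaps) + 1]] <- list(t = st$t, u = fl$u, v = fl$v,
                                         w = fl$w, p = fl$p)
  }
  structure(list(track = track, rot = rotm, joints = qjm,
                 joint_torques = taum, state = st, fluid = fl,
                 model = model, stroke = stroke, preset = preset,
                 active_limbs = active_limbs, config = config,
                 period = period, snapshots = snaps,
                 heading0 = c(1, 0, 0)),
            class = "psw_trajectory")
}

# anatomical 12-vector (degrees) of the start pose
start_pose <- function(preset, active_limbs) {
  one <- function(lb) {
    if (active_limbs == "all" || active_limbs == lb) preset$abducted[[lb]]
    else preset$neutral[[lb]]
  }
  fore <- one("fore"); hind <- one("hind")
  out <- c(fore, fore, hind, hind)
  names(out) <- paste0(rep(c("fore_left", "fore_right", "hind_left",
                             "hind_right"), each = 3),
                       ".", rep(c("dv", "ap", "rot"), 4))
  out
}

#' Straight-swimming quality of a trajectory
#'
#' Metrics are computed over the second stroke cycle only (the first,
#' started from rest, is excluded): forward distance is the COM
#' displacement projected on the initial heading; directional deviation is
#' the perpendicular COM displacement (lateral and vertical); orientation
#' deviation is the geodesic angle between the start- and end-of-cycle
#' base orientations.  The score is
#' `q = forward - w_dir * ||d_perp|| - w_orient * |dtheta|`.
#'
#' @param traj A `psw_trajectory` spanning at least 2 cycles.
#' @param w_dir Penalty weight on perpendicular displacement (m per m).
#' @param w_orient Penalty weight on orientation change (m per rad).
#' @param cycle Which cycle to evaluate (default 2).
#' @return A `psw_quality` list with `forward_distance`,
#'   `lateral_deviation`, `vertical_deviation`, `orientation_deviation`,
#'   `mean_speed` and `quality`.
#' @export
quality <- function(traj, w_dir = 1, w_orient = 0.5, cycle = 2) {
  period <- traj$period
  tr <- traj$track
  if (max(tr$t) < cycle * period - 1e-9)
    stop("trajectory too short: needs at least ", cycle, " stroke cycles")
  i0 <- which.min(abs(tr$t - (cycle - 1) * period))
  i1 <- which.min(abs(tr$t - cycle * period))
  d <- as.numeric(tr[i1, c("x", "y", "z")] - tr[i0, c("x", "y", "z")])
  h0 <- traj$heading0
  fwd <- sum(d * h0)
  dperp <- d - fwd * h0
  # decompose perpendicular into lateral (world y) and vertical (world z)
  up <- c(0, 0, 1)
  left <- cross3(up, h0)
  lat <- sum(dperp * left)
  vert <- sum(dperp * up)
  R0 <- matrix(traj$rot[i0, ], 3, 3)
  R1 <- matrix(traj$rot[i1, ], 3, 3)
  dth <- rot_angle(R0, R1)
  qv <- fwd - w_dir * sqrt(sum(dperp^2)) - w_orient * abs(dth)
  structure(list(forward_distance = fwd, lateral_deviation = lat,
                 vertical_deviation = vert, orientation_deviation = dth,
                 perp_deviation = sqrt(sum(dperp^2)),
                 mean_speed = fwd / period, quality = qv, cycle = cycle),
            class = "psw_quality")
}

#' @export
print.psw_quality <- function(x, ...) {
  cat(sprintf(
    "cycle %d: forward %.3f m (%.3f m/s), lateral %.4f m, vertical %.4f m,\n  orientation %.3f rad, quality %.3f\n",
    x$cycle, x$forward_distance, x$mean_speed, x$lateral_deviation,
    x$vertical_deviation, x$orientation_deviation, x$quality))
  invisible(x)
}

#' Distal flipper-tip paths
#'
#' Forward-kinematics position of each flipper's distal tip at every
#' recorded tick (the white tip traces of the underwater-flight figures).
#'
#' @param traj A `psw_trajectory`.
#' @return A data frame with time, limb name and tip position columns.
#' @export
tip_traces <- function(traj) {
  model <- traj$model
  tips <- lapply(model_joints(model), function(nm) {
    V <- model$body$links[[nm]]$vertices
    V[which.max(abs(V[, 2])), ]   # most distal vertex along the span
  })
  names(tips) <- model_joints(model)
  tr <- traj$track
  out <- list()
  for (i in seq_len(nrow(tr))) {
    Rb <- matrix(traj$rot[i, ], 3, 3)
    kin <- fk(model, as.numeric(tr[i, c("bx", "by", "bz")]),
              Rb, traj$joints[i, ])
    for (nm in model_joints(model)) {
      p <- kin[[nm]]$t + kin[[nm]]$R %*% tips[[nm]]
      out[[length(out) + 1]] <- data.frame(
        t = tr$t[i], limb = nm, x = p[1], y = p[2], z = p[3])
    }
  }
  do.call(rbind, out)
}

#' Massless-particle traces filtered by vorticity
#'
#' Advects passive particles through the saved velocity-field snapshots
#' and keeps only trace segments where the local vorticity magnitude
#' exceeds the threshold (default 1.5 1/s), concentrating the traces at
#' regions of interest.
#'
#' @param traj A `psw_trajectory` run with `snapshot_every > 0`.
#' @param n_particles Number of seeded particles.
#' @param vorticity_threshold Threshold in 1/s; `Inf` yields no traces.
#' @param seed RNG seed for particle seeding.
#' @return Data frame of trace segments (particle id, time, position).
#' @export
particle_traces <- function(traj, n_particles = 500,
                            vorticity_threshold = 1.5, seed = 1) {
  if (!length(traj$snapshots))
    stop("trajectory has no field snapshots; rerun with snapshot_every > 0")
  grid <- traj$config$grid
  set.seed(seed)
  P <- cbind(runif(n_particles, grid$origin[1], grid$origin[1] + grid$domain[1]),
             runif(n_particles, grid$origin[2], grid$origin[2] + grid$domain[2]),
             runif(n_particles, grid$origin[3], grid$origin[3] + grid$domain[3]))
  out <- list()
  tprev <- traj$snapshots[[1]]$t
  for (si in seq_along(traj$snapshots)) {
    sn <- traj$snapshots[[si]]
    dt <- if (si == 1) 0 else sn$t - tprev
    tprev <- sn$t
    loc <- P - rep(grid$origin, each = n_particles)
    vel <- cpp_interp_velocity(sn$u, sn$v, sn$w, grid$n, grid$dx, loc)
    if (dt > 0) P <- P + dt * vel
    vort <- vorticity_magnitude(sn, grid)
    ijk <- pmin(pmax(floor((P - rep(grid$origin, each = n_particles)) /
                             grid$dx) + 1, 1),
                matrix(rep(grid$n, each = n_particles), ncol = 3))
    vmag <- vort[cbind(ijk[, 1], ijk[, 2], ijk[, 3])]
    keep <- which(is.finite(vmag) & vmag > vorticity_threshold)
    if (length(keep))
      out[[length(out) + 1]] <- data.frame(
        id = keep, t = sn$t, x = P[keep, 1], y = P[keep, 2], z = P[keep, 3],
        vorticity = vmag[keep])
  }
  if (!length(out))
    return(data.frame(id = integer(0), t = numeric(0), x = numeric(0),
                      y = numeric(0), z = numeric(0), vorticity = numeric(0)))
  do.call(rbind, out)
}

# cell-centered vorticity magnitude from a snapshot
vorticity_magnitude <- function(sn, grid) {
  n <- grid$n
  dx <- grid$dx
  uc <- (sn$u[1:n[1], , , drop = FALSE] + sn$u[2:(n[1] + 1), , , drop = FALSE]) / 2
  vc <- (sn$v[, 1:n[2], , drop = FALSE] + sn$v[, 2:(n[2] + 1), , drop = FALSE]) / 2
  wc <- (sn$w[, , 1:n[3], drop = FALSE] + sn$w[, , 2:(n[3] + 1), drop = FALSE]) / 2
  dd <- function(a, axis) {
    # central difference along axis with one-sided ends
    nn <- dim(a)[axis]
    idx <- function(i) {
      ix <- as.list(rep(TRUE, 3)); ix[[axis]] <- i
      do.call(`[`, c(list(a), ix, list(drop = FALSE)))
    }
    out <- (idx(c(2:nn, nn)) - idx(c(1, 1:(nn - 1)))) / (2 * dx)
    array(out, dim(a))
  }
  cx <- dd(wc, 2) - dd(vc, 3)
  cy <- dd(uc, 3) - dd(wc, 1)
  cz <- dd(vc, 1) - dd(uc, 2)
  sqrt(cx^2 + cy^2 + cz^2)
}

#' Save a trajectory's track to CSV
#' @param traj A `psw_trajectory`.
#' @param path Output file.
#' @export
write_trajectory <- function(traj, path) {
  df <- cbind(traj$track, as.data.frame(traj$joints))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
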