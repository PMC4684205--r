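# Simulation orchestration and the straight-swimming quality function.

# build a synthetic trajectory object with a prescribed COM path
synthetic_traj <- function(com_fun, rot_fun = function(t) diag(3),
                           period = 2, n_cycles = 2, dt = 0.05,
                           heading0 = c(1, 0, 0)) {
  t <- seq(0, n_cycles * period, by = dt)
  com <- t(vapply(t, com_fun, numeric(3)))
  rot <- t(vapply(t, function(ti) as.vector(rot_fun(ti)), numeric(9)))
  structure(list(
    track = data.frame(t = t, x = com[, 1], y = com[, 2], z = com[, 3],
                       bx = com[, 1], by = com[, 2], bz = com[, 3]),
    rot = rot, joints = matrix(0, length(t), 12),
    period = period, heading0 = heading0), class = "psw_trajectory")
}

test_that("quality metrics match a hand-built straight trajectory", {
  # 0.92 m forward per cycle along the initial heading, no deviation
  traj <- synthetic_traj(function(t) c(0.46 * t, 0, 0))
  q <- quality(traj)
  expect_equal(q$forward_distance, 0.92, tolerance = 1e-9)
  expect_equal(q$mean_speed, 0.46, tolerance = 1e-9)
  expect_equal(q$lateral_deviation, 0)
  expect_equal(q$vertical_deviation, 0)
  expect_equal(q$orientation_deviation, 0)
  expect_equal(q$quality, 0.92, tolerance = 1e-9)
})

test_that("pure sideways displacement scores negative quality", {
  traj <- synthetic_traj(function(t) c(0, 0.2 * t, 0))
  q <- quality(traj)
  expect_equal(q$forward_distance, 0, tolerance = 1e-12)
  expect_lt(q$quality, 0)
})

test_that("quality is invariant under rotation of the whole experiment", {
  R <- rot_z(0.7) %*% rot_y(-0.25)
  com <- function(t) c(0.3 * t, 0.02 * sin(pi * t), 0.01 * t)
  traj1 <- synthetic_traj(com)
  traj2 <- synthetic_traj(function(t) as.vector(R %*% com(t)),
                          rot_fun = function(t) R,
                          heading0 = as.vector(R %*% c(1, 0, 0)))
  q1 <- quality(traj1)
  q2 <- quality(traj2)
  expect_equal(q2$forward_distance, q1$forward_distance, tolerance = 1e-9)
  expect_equal(q2$perp_deviation, q1$perp_deviation, tolerance = 1e-9)
  expect_equal(q2$quality, q1$quality, tolerance = 1e-9)
})

test_that("quality demands at least the requested number of cycles", {
  traj <- synthetic_traj(function(t) c(0.3 * t, 0, 0), n_cycles = 1)
  expect_error(quality(traj), "too short")
})

test_that("simulated trajectories have the configured duration and sampling", {
  cfg <- sim_config("mini", dt = 0.025, n_cycles = 2)
  traj <- fix_neutral_sim()
  expect_equal(nrow(traj$track), 2 * 2 / 0.025 + 1)
  expect_equal(max(traj$track$t), 4, tolerance = 1e-9)
  expect_equal(unique(round(diff(traj$track$t), 12)), 0.025)
})

test_that("a zero-amplitude stroke produces essentially no travel", {
  traj <- fix_neutral_sim()
  q <- quality(traj)
  expect_lt(abs(q$forward_distance), 0.02)
})

test_that("tip traces are a point for static limbs and planar for pure dorsoventral motion", {
  model <- fix_model()
  preset <- fix_preset()
  # static: neutral stroke targets, frame angles constant
  qj <- plesioswim:::anatomical_to_frame(
    model, joint_targets(neutral_stroke(preset), 0, "all", preset))
  t <- seq(0, 2, by = 0.1)
  make_traj <- function(qfun) {
    structure(list(
      track = data.frame(t = t, x = 0, y = 0, z = 0, bx = 0, by = 0, bz = 0),
      rot = matrix(rep(as.vector(diag(3)), length(t)), length(t), 9,
                   byrow = TRUE),
      joints = t(vapply(t, qfun, numeric(12))),
      model = model, period = 2, heading0 = c(1, 0, 0)),
      class = "psw_trajectory")
  }
  tips <- tip_traces(make_traj(function(ti) qj))
  one <- tips[tips$limb == "fore_left", ]
  expect_lt(max(dist(one[, c("x", "y", "z")])), 1e-12)
  # dorsoventral-only oscillation: tip stays in a transverse plane (x const)
  dvst <- stroke_params(
    fore = limb_stroke(dv = sinusoid_spec(-30, 20), ap = sinusoid_spec(0, 0),
                       rot = sinusoid_spec(0, 0)),
    hind = limb_stroke(dv = sinusoid_spec(0, 0), ap = sinusoid_spec(0, 0),
                       rot = sinusoid_spec(0, 0)))
  qfun <- function(ti) plesioswim:::anatomical_to_frame(
    model, joint_targets(dvst, ti, "all", preset))
  tips2 <- tip_traces(make_traj(qfun))
  fl2 <- tips2[tips2$limb == "fore_left", ]
  expect_lt(diff(range(fl2$x)), 1e-9)        # transverse arc: constant x
  expect_gt(diff(range(fl2$z)), 0.3)         # but genuinely moving
})

test_that("particle traces follow the vorticity threshold contract", {
  traj <- cached("snap_sim", {
    cfg <- sim_config("mini", dt = 0.025, n_cycles = 1, snapshot_every = 10)
    run_simulation(fix_body_mini(), fix_stroke(), fix_preset(), "all", cfg)
  })
  expect_gt(length(traj$snapshots), 0)
  tr_inf <- particle_traces(traj, n_particles = 200,
                            vorticity_threshold = Inf)
  expect_equal(nrow(tr_inf), 0)
  tr0 <- particle_traces(traj, n_particles = 200, vorticity_threshold = 0.05)
  expect_gt(nrow(tr0), 0)
  expect_true(all(tr0$vorticity > 0.05))
})

test_that("the gait phase diagnostic recovers the encoded fore-hind offset", {
  preset <- fix_preset()
  for (offset in c(0, 0.25)) {
    st <- stroke_params(
      fore = limb_stroke(dv = sinusoid_spec(-30, 20, phase = 0),
                         ap = sinusoid_spec(-10, 0),
                         rot = sinusoid_spec(0, 0)),
      hind = limb_stroke(dv = sinusoid_spec(-35, 10, phase = offset),
                         ap = sinusoid_spec(-30, -20),
                         rot = sinusoid_spec(0, 0)))
    t <- seq(0, 8, by = 0.02)
    fore_dv <- eval_dof(st$fore$dv, 0, t, 2)
    hind_dv <- eval_dof(st$hind$dv, 0, t, 2)
    cc <- ccf(hind_dv, fore_dv, lag.max = 50, plot = FALSE)
    lag <- cc$lag[which.max(cc$acf)] * 0.02
    d <- abs(((-lag / 2) %% 1) - offset)
    expect_lt(min(d, 1 - d), 0.015)   # within the lag-grid resolution
  }
})

test_that("trajectory export writes a readable CSV", {
  traj <- fix_neutral_sim()
  f <- tempfile(fileext = ".csv")
  write_trajectory(traj, f)
  df <- read.csv(f)
  expect_equal(nrow(df), nrow(traj$track))
  expect_true(all(c("t", "x", "y", "z") %in% names(df)))
})
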