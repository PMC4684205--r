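# Articulated rigid-body dynamics: mass matrix, bias forces, Stable-PD,
# integration, and surface-point kinematics.

test_that("free box mass matrix equals the closed-form rigid-body inertia", {
  b <- rigid_body(box_mesh(0.4, 0.3, 0.2), density = 1000)
  model <- dynamics_model(b)
  st <- init_state(qj = numeric(0))
  st$Rb <- rot_z(0.3) %*% rot_x(-0.2)
  M <- mass_matrix(model, st)
  m <- 1000 * 0.4 * 0.3 * 0.2
  Ibody <- m / 12 * diag(c(0.3^2 + 0.2^2, 0.4^2 + 0.2^2, 0.4^2 + 0.3^2))
  Iw <- st$Rb %*% Ibody %*% t(st$Rb)
  expect_lt(max(abs(M[1:3, 1:3] - diag(m, 3))), 1e-10)
  expect_lt(max(abs(M[4:6, 4:6] - Iw)), 1e-10)
  expect_lt(max(abs(M[1:3, 4:6])), 1e-10)
})

test_that("mass matrix is symmetric positive definite across random states", {
  model <- fix_model()
  set.seed(7)
  for (i in 1:100) {
    st <- init_state(x = rnorm(3), qj = runif(12, -1, 1))
    st$Rb <- exp_so3(rnorm(3))
    M <- mass_matrix(model, st)
    expect_identical(M, t(M))
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("bias forces vanish at rest and scale quadratically with velocity", {
  model <- fix_model()
  st <- init_state(qj = runif(12, -0.5, 0.5))
  expect_equal(bias_forces(model, st), numeric(18))
  st$v <- c(0.2, -0.1, 0.3)
  st$om <- c(0.5, -0.4, 0.2)
  st$qdj <- runif(12, -1, 1)
  C1 <- bias_forces(model, st)
  st2 <- st
  st2$v <- 2 * st$v; st2$om <- 2 * st$om; st2$qdj <- 2 * st$qdj
  C2 <- bias_forces(model, st2)
  expect_equal(C2, 4 * C1, tolerance = 1e-10)
})

test_that("a freely spinning rigid body conserves kinetic energy", {
  b <- rigid_body(box_mesh(0.5, 0.3, 0.2), density = 1000)
  model <- dynamics_model(b)
  st <- init_state(qj = numeric(0))
  # dominant-axis spin with wobble, the regime a flapping limb works in
  st$om <- c(0.15, 0.3, 2.4)
  energy <- function(s) {
    M <- mass_matrix(model, s)
    gv <- c(s$v, s$om)
    0.5 * sum(gv * (M %*% gv))
  }
  e0 <- energy(st)
  for (i in 1:1000) st <- integrate_state(model, st, numeric(6), 1e-3)
  expect_lt(abs(energy(st) - e0) / e0, 1e-3)
})

test_that("Stable-PD tracks a step target where explicit PD diverges", {
  # 1-DOF pendulum-like joint: I theta'' = tau, kp dt^2 > I
  I <- 0.05; kp <- 4000; kd <- 120; dt <- 0.01; target <- 0.6
  run <- function(spd) {
    th <- 0; thd <- 0
    for (i in 1:100) {
      if (spd) {
        tau <- -kp * (th + dt * thd - target) - kd * thd
        thdd <- tau / (I + kd * dt)     # implicit damping
      } else {
        tau <- -kp * (th - target) - kd * thd
        thdd <- tau / I
      }
      thd <- thd + dt * thdd
      th <- th + dt * thd
      if (!is.finite(th) || abs(th) > 1e6) return(Inf)
    }
    abs(th - target) / target
  }
  expect_gt(kp * dt^2, I)
  expect_lt(run(TRUE), 0.02)      # settles within 2% inside 1 s
  expect_equal(run(FALSE), Inf)   # explicit PD at the same gains blows up
})

test_that("spd_torques is zero on-target and linear in position error", {
  model <- fix_model()
  st <- init_state(qj = rep(0.1, 12))
  st$qdj <- rep(0.2, 12)
  tgt <- st$qj + 0.01 * st$qdj    # dt * qdot predictor exactly on target
  tau0 <- spd_torques(model, st, tgt, st$qdj, 0.01)
  expect_equal(tau0, numeric(18))
  tau1 <- spd_torques(model, st, tgt + 0.1, st$qdj, 0.01)
  tau2 <- spd_torques(model, st, tgt + 0.2, st$qdj, 0.01)
  expect_equal(tau2[7:18] - tau0[7:18], 2 * (tau1[7:18] - tau0[7:18]),
               tolerance = 1e-12)
  expect_equal(tau1[1:6], numeric(6))   # no torque on base DOFs
})

test_that("a constant force from rest reproduces the ballistic closed form", {
  model <- fix_model()
  st <- init_state()
  f <- c(12, 0, 0)
  mtot <- sum(vapply(model$links, `[[`, 0, "mass"))
  x0 <- body_momentum(model, st)$com
  for (i in 1:1000)
    st <- integrate_state(model, st, c(f, numeric(15)), 1e-3)
  dx <- body_momentum(model, st)$com[1] - x0[1]
  expect_equal(dx, 0.5 * f[1] / mtot * 1^2, tolerance = 0.01)
})

test_that("flapping in vacuum produces no net momentum change", {
  model <- fix_model()
  preset <- fix_preset()
  stroke <- fix_stroke()
  st <- init_state()
  dt <- 1e-3
  mom0 <- body_momentum(model, st)$momentum
  peak <- 0
  for (i in 1:1000) {
    t2 <- st$t + dt
    tgt <- plesioswim:::anatomical_to_frame(
      model, joint_targets(stroke, t2, "all", preset))
    tgtd <- (plesioswim:::anatomical_to_frame(
      model, joint_targets(stroke, t2 + 1e-4, "all", preset)) - tgt) / 1e-4
    tau <- spd_torques(model, st, tgt, tgtd, dt)
    st <- integrate_state(model, st, tau, dt, implicit_damping = TRUE)
    peak <- max(peak, sqrt(sum(body_momentum(model, st)$momentum^2)))
  }
  drift <- sqrt(sum((body_momentum(model, st)$momentum - mom0)^2))
  # base momentum must stay constant: internal torques cannot self-propel
  expect_lt(drift, 0.05)
  expect_lt(drift, 0.05 * max(peak, 1))
})

test_that("surface-point Jacobians match finite differences of positions", {
  model <- fix_model()
  set.seed(3)
  st <- init_state(x = c(0.3, -0.2, 0.1), qj = runif(12, -0.6, 0.6))
  st$Rb <- exp_so3(c(0.2, -0.1, 0.3))
  pts <- matrix(c(1.2, 0.6, 0.1, -0.4, -0.8, -0.2), 2, 3, byrow = TRUE)
  link <- c("fore_left", "hind_right")
  ik <- interface_kinematics(model, st, pts, link)
  # finite-difference columns for the 12 joint DOFs
  h <- 1e-6
  for (pi in 1:2) {
    loc <- solve(plesioswim:::fk(model, st$x, st$Rb, st$qj)[[link[pi]]]$R,
                 pts[pi, ] - plesioswim:::fk(model, st$x, st$Rb,
                                             st$qj)[[link[pi]]]$t)
    for (d in 1:12) {
      qp <- st$qj; qp[d] <- qp[d] + h
      qm <- st$qj; qm[d] <- qm[d] - h
      kp <- plesioswim:::fk(model, st$x, st$Rb, qp)[[link[pi]]]
      km <- plesioswim:::fk(model, st$x, st$Rb, qm)[[link[pi]]]
      fd <- ((kp$t + kp$R %*% loc) - (km$t + km$R %*% loc)) / (2 * h)
      expect_equal(as.vector(ik$jacobian[[pi]][, 6 + d]), as.vector(fd),
                   tolerance = 1e-5)
    }
  }
})

test_that("surface velocities follow base translation and joint rotation", {
  model <- fix_model()
  st <- init_state(qj = rep(0, 12))
  pt <- matrix(c(0.8, 1.0, -0.05), 1, 3)
  ik0 <- interface_kinematics(model, st, pt, "fore_left")
  expect_equal(as.vector(ik0$velocity), c(0, 0, 0))
  # pure base translation
  st$v <- c(0.7, -0.2, 0.1)
  ik1 <- interface_kinematics(model, st, pt, "fore_left")
  expect_equal(as.vector(ik1$velocity), st$v)
  # single revolute rate: |v| = omega * r about the joint axis
  st$v <- c(0, 0, 0)
  st$qdj <- c(1.3, rep(0, 11))    # fore_left dv rate
  kin <- plesioswim:::fk(model, st$x, st$Rb, st$qj)
  P <- kin$fore_left$P
  a <- kin$fore_left$axes[, 1]
  r <- pt[1, ] - P
  rperp <- r - sum(r * a) * a
  ik2 <- interface_kinematics(model, st, pt, "fore_left")
  expect_equal(sqrt(sum(ik2$velocity^2)), 1.3 * sqrt(sum(rperp^2)),
               tolerance = 1e-10)
  expect_error(interface_kinematics(model, st, pt, "fin"), "attributed")
})

test_that("integration aborts cleanly on non-finite accelerations", {
  model <- fix_model()
  st <- init_state()
  expect_error(integrate_state(model, st, rep(NaN, 18), 0.01), "non-finite")
})
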