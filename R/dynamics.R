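# Articulated rigid-body dynamics in generalized coordinates.
#
# Generalized velocity (18-vector): base linear velocity (world, 3), base
# angular velocity (world, 3), then 12 joint rates ordered fore_left,
# fore_right, hind_left, hind_right x (dv, ap, rot).  The base orientation
# is stored as a rotation matrix and integrated through the exponential
# map, so pitch beyond +/-90 degrees is singularity-free.  Joint rotations
# compose as R_z(ap) R_x(dv) R_y(rot) about the pivot; right-side joints
# store the sign-flipped (frame) angle of the anatomical value so that
# mirrored motion is exact.

JOINT_NAMES <- c("fore_left", "fore_right", "hind_left", "hind_right")

# joints present in a model (a single free rigid body has none)
model_joints <- function(model) names(model$pivots)
model_ndof <- function(model) 6 + 3 * length(model$pivots)

#' Build the dynamics model from an articulated body
#'
#' Computes per-link mass, center of mass and inertia from the uniform
#' density watertight meshes, and stores joint placement and PD gains.
#'
#' @param body A [build_swimmer()] result.
#' @param kp,kd Stable-PD gains per joint DOF (N m/rad, N m s/rad).
#' @return A `psw_model` list.
#' @export
dynamics_model <- function(body, kp = 4000, kd = 200) {
  links <- lapply(names(body$links), function(nm) {
    pr <- body$props[[nm]]
    list(name = nm, mass = pr$mass, com = pr$com, inertia = pr$inertia,
         volume = pr$volume)
  })
  names(links) <- names(body$links)
  nj <- 3 * length(body$pivots)
  structure(list(
    links = links, pivots = body$pivots, side = body$side,
    kp = rep(kp, nj), kd = rep(kd, nj), body = body),
    class = "psw_model")
}

#' Wrap a single mesh as a free rigid body
#'
#' Produces a one-link `psw_body` with no joints, usable with the same
#' dynamics and coupling machinery as the articulated swimmer (6 free
#' DOFs); used for validation against closed-form rigid-body oracles.
#'
#' @param m A watertight `psw_mesh` (vertices in the body frame; the frame
#'   origin is moved to the COM).
#' @param density Uniform density in kg/m^3.
#' @return A `psw_body` with a single `torso` link.
#' @export
rigid_body <- function(m, density = 1000) {
  pr <- mesh_mass_props(m, density)
  m <- mesh_transform(m, t = -pr$com)
  pr <- mesh_mass_props(m, density)
  pr$com <- c(0, 0, 0)
  structure(list(links = list(torso = m), props = list(torso = pr),
                 pivots = list(), side = numeric(0), density = density,
                 spec = NULL),
            class = "psw_body")
}

#' Initial articulated state
#'
#' @param x,Rb Base position (world, torso COM) and orientation.
#' @param qj 12 joint angles in radians, frame convention.
#' @param t Time.
#' @return A `psw_state` list with zero velocities.
#' @export
init_state <- function(x = c(0, 0, 0), Rb = diag(3), qj = rep(0, 12), t = 0) {
  structure(list(x = x, Rb = Rb, qj = qj, v = c(0, 0, 0), om = c(0, 0, 0),
                 qdj = numeric(length(qj)), t = t), class = "psw_state")
}

# anatomical (degrees) -> frame (radians) joint vector.
# For the left side: dorsal (+dv) is a positive rotation about the
# anterior axis, while anterior (+ap) sweep and supination (+rot) are
# negative rotations about their axes.  The right side is the sagittal
# mirror M R M: rotations about the in-plane axes (dv about x, ap about z)
# flip sign, but rotation about the mirror normal (rot about y) does not,
# so the rot sign is side-independent.  This makes mirrored anatomical
# motion exact: R_right(t) = M R_left(t) M.
anatomical_to_frame <- function(model, ang12_deg) {
  sides <- unname(model$side[model_joints(model)])
  sgn <- as.vector(rbind(sides, -sides, rep(-1, length(sides))))
  deg2rad(unname(ang12_deg)) * sgn
}

# inverse mapping: frame (radians) -> anatomical (degrees)
frame_to_anatomical <- function(model, qj) {
  sides <- unname(model$side[model_joints(model)])
  sgn <- as.vector(rbind(sides, -sides, rep(-1, length(sides))))
  rad2deg(qj) * sgn
}

# forward kinematics: world placement of every link plus joint axes
fk <- function(model, x, Rb, qj) {
  out <- list(torso = list(R = Rb, t = x, com = x + Rb %*% model$links$torso$com))
  jn <- model_joints(model)
  for (ji in seq_along(jn)) {
    nm <- jn[ji]
    q <- qj[(3 * ji - 2):(3 * ji)]       # (dv, ap, rot)
    Rj <- rot_z(q[2]) %*% rot_x(q[1]) %*% rot_y(q[3])
    P <- x + Rb %*% model$pivots[[nm]]
    Rl <- Rb %*% Rj
    a_ap <- Rb %*% c(0, 0, 1)
    a_dv <- Rb %*% rot_z(q[2]) %*% c(1, 0, 0)
    a_rot <- Rb %*% rot_z(q[2]) %*% rot_x(q[1]) %*% c(0, 1, 0)
    com <- P + Rl %*% model$links[[nm]]$com
    out[[nm]] <- list(R = Rl, t = as.vector(P), com = as.vector(com),
                      P = as.vector(P),
                      axes = cbind(a_dv, a_ap, a_rot, deparse.level = 0))
  }
  out$torso$com <- as.vector(out$torso$com)
  out
}

# pose in the form used by voxelize(): per link R and t
fk_pose <- function(kin) lapply(kin, function(l) list(R = l$R, t = l$t))

# 6 x ndof link Jacobian rows (v_com; omega) for each link
link_jacobians <- function(model, kin, x) {
  nd <- model_ndof(model)
  L <- list()
  base <- function(com) {
    J <- matrix(0, 6, nd)
    J[1:3, 1:3] <- diag(3)
    J[1:3, 4:6] <- -skew3(com - x)
    J[4:6, 4:6] <- diag(3)
    J
  }
  L$torso <- base(kin$torso$com)
  jn <- model_joints(model)
  for (ji in seq_along(jn)) {
    nm <- jn[ji]
    k <- kin[[nm]]
    J <- base(k$com)
    cols <- 6 + (3 * ji - 2):(3 * ji)
    for (d in 1:3) {
      a <- k$axes[, d]
      J[1:3, cols[d]] <- cross3(a, k$com - k$P)
      J[4:6, cols[d]] <- a
    }
    L[[nm]] <- J
  }
  L
}

#' Generalized mass matrix
#'
#' @param model A [dynamics_model()].
#' @param state A `psw_state` (only the configuration is used).
#' @return Symmetric positive-definite ndof x ndof matrix (18x18 for the
#'   four-flippered swimmer).
#' @export
mass_matrix <- function(model, state) {
  kin <- fk(model, state$x, state$Rb, state$qj)
  L <- link_jacobians(model, kin, state$x)
  nd <- model_ndof(model)
  M <- matrix(0, nd, nd)
  for (nm in names(model$links)) {
    lk <- model$links[[nm]]
    Iw <- kin[[nm]]$R %*% lk$inertia %*% t(kin[[nm]]$R)
    Jl <- L[[nm]]
    M <- M + lk$mass * crossprod(Jl[1:3, , drop = FALSE]) +
      t(Jl[4:6, , drop = FALSE]) %*% Iw %*% Jl[4:6, , drop = FALSE]
  }
  (M + t(M)) / 2
}

# per-link spatial velocity and bias acceleration (at qdd = 0)
link_motion <- function(model, kin, x, v, om, qdj) {
  out <- list()
  out$torso <- list(
    omega = om,
    vcom = v + cross3(om, kin$torso$com - x),
    alpha_bias = c(0, 0, 0),
    acom_bias = cross3(om, cross3(om, kin$torso$com - x)))
  jn <- names(kin)[-1]
  for (ji in seq_along(jn)) {
    nm <- jn[ji]
    k <- kin[[nm]]
    qd <- qdj[(3 * ji - 2):(3 * ji)]    # (dv, ap, rot) rates
    a_dv <- k$axes[, 1]; a_ap <- k$axes[, 2]; a_rot <- k$axes[, 3]
    # rotation order: ap (z) applied first, then dv, then rot
    omega <- om + qd[2] * a_ap + qd[1] * a_dv + qd[3] * a_rot
    adot_ap <- cross3(om, a_ap)
    adot_dv <- cross3(om + qd[2] * a_ap, a_dv)
    adot_rot <- cross3(om + qd[2] * a_ap + qd[1] * a_dv, a_rot)
    alpha <- qd[2] * adot_ap + qd[1] * adot_dv + qd[3] * adot_rot
    r_pc <- k$com - k$P
    r_bp <- k$P - x
    vP <- v + cross3(om, r_bp)
    om_rel <- qd[2] * a_ap + qd[1] * a_dv + qd[3] * a_rot
    vcom <- vP + cross3(omega, r_pc)
    aP <- cross3(om, cross3(om, r_bp))
    acom <- aP + cross3(alpha, r_pc) + cross3(omega, cross3(omega, r_pc))
    out[[nm]] <- list(omega = omega, vcom = vcom, alpha_bias = alpha,
                      acom_bias = acom, om_rel = om_rel)
  }
  out
}

#' Coriolis and centrifugal bias forces
#'
#' Generalized bias `C(q, qdot)` such that the equations of motion read
#' `M(q) qddot + C = tau_int + tau_ext`; computed from exact per-link bias
#' accelerations (inverse dynamics at zero generalized acceleration,
#' gravity excluded).
#'
#' @param model A [dynamics_model()].
#' @param state A `psw_state`.
#' @return ndof-vector.
#' @export
bias_forces <- function(model, state) {
  kin <- fk(model, state$x, state$Rb, state$qj)
  L <- link_jacobians(model, kin, state$x)
  mo <- link_motion(model, kin, state$x, state$v, state$om, state$qdj)
  C <- numeric(model_ndof(model))
  for (nm in names(model$links)) {
    lk <- model$links[[nm]]
    Iw <- kin[[nm]]$R %*% lk$inertia %*% t(kin[[nm]]$R)
    f <- lk$mass * mo[[nm]]$acom_bias
    tq <- Iw %*% mo[[nm]]$alpha_bias +
      cross3(mo[[nm]]$omega, as.vector(Iw %*% mo[[nm]]$omega))
    C <- C + as.vector(t(L[[nm]][1:3, , drop = FALSE]) %*% f) +
      as.vector(t(L[[nm]][4:6, , drop = FALSE]) %*% tq)
  }
  C
}

# generalized gravity force (world g acting at each link COM)
gravity_force <- function(model, state, g = c(0, 0, -9.81)) {
  kin <- fk(model, state$x, state$Rb, state$qj)
  L <- link_jacobians(model, kin, state$x)
  tau <- numeric(model_ndof(model))
  for (nm in names(model$links))
    tau <- tau + model$links[[nm]]$mass *
      as.vector(t(L[[nm]][1:3, , drop = FALSE]) %*% g)
  tau
}

# net gravity minus analytic buoyancy on a fully submerged body.  The
# coupled solve works with dynamic pressure (total minus hydrostatic):
# gravity on the fluid and the hydrostatic pressure gradient cancel
# exactly, and the hydrostatic surface integral over each closed link is
# Archimedes' rho_f * V * g acting at the link centroid, which for a
# uniform-density link is its COM.  The body therefore feels only the
# imbalance (m_l - rho_f V_l) g, exactly zero at neutral buoyancy.
gravity_buoyancy_force <- function(model, state, rho_fluid = 1000,
                                   g = c(0, 0, -9.81)) {
  kin <- fk(model, state$x, state$Rb, state$qj)
  L <- link_jacobians(model, kin, state$x)
  tau <- numeric(model_ndof(model))
  for (nm in names(model$links)) {
    lk <- model$links[[nm]]
    net <- (lk$mass - rho_fluid * lk$volume)
    if (net != 0)
      tau <- tau + net * as.vector(t(L[[nm]][1:3, , drop = FALSE]) %*% g)
  }
  tau
}

#' Stable-PD joint torques
#'
#' Implicit-damping PD law evaluated per joint DOF:
#' `tau = -kp * (q + dt*qdot - qbar) - kd * (qdot - qbardot)`, where `qbar`
#' is the target angle at the end of the step.  No torque acts on the six
#' base DOFs.
#'
#' @param model A [dynamics_model()].
#' @param state A `psw_state`.
#' @param q_target,qd_target Target joint angles (rad, frame convention)
#'   and rates (rad/s), 12-vectors.
#' @param dt Time step in seconds.
#' @return ndof-vector of generalized torques (zeros on the base DOFs).
#' @export
spd_torques <- function(model, state, q_target, qd_target, dt) {
  tauj <- -model$kp * (state$qj + dt * state$qdj - q_target) -
    model$kd * (state$qdj - qd_target)
  c(numeric(6), tauj)
}

#' Semi-implicit Euler step of the articulated body
#'
#' Solves `M qddot = tau - C`, advances velocities first and then
#' positions; the base orientation is updated through the rotation
#' exponential.
#'
#' @param model A [dynamics_model()].
#' @param state A `psw_state`.
#' @param tau Generalized force ndof-vector (internal + external).
#' @param dt Time step in seconds.
#' @param implicit_damping If `TRUE`, the Stable-PD damping term
#'   `-kd * dt * qddot` is folded into the mass matrix (the implicit part
#'   of the SPD law); use whenever `tau` contains SPD joint torques.
#' @return Updated `psw_state`.
#' @export
integrate_state <- function(model, state, tau, dt, implicit_damping = FALSE) {
  M <- mass_matrix(model, state)
  C <- bias_forces(model, state)
  if (implicit_damping)
    M <- M + diag(c(numeric(6), model$kd * dt))
  qdd <- solve(M, tau - C)
  if (any(!is.finite(qdd)))
    stop("non-finite generalized accelerations; simulation aborted at t = ",
         state$t)
  gv <- c(state$v, state$om, state$qdj) + dt * qdd
  state$v <- gv[1:3]
  state$om <- gv[4:6]
  if (length(gv) > 6) state$qdj <- gv[-(1:6)] else state$qdj <- numeric(0)
  state$x <- state$x + dt * state$v
  state$Rb <- orthonormalize(exp_so3(state$om * dt) %*% state$Rb)
  state$qj <- state$qj + dt * state$qdj
  state$t <- state$t + dt
  state
}

#' Kinematics of body-surface points
#'
#' For points attached to given links, returns the 3 x ndof Jacobian rows, the
#' instantaneous surface velocity `J qdot`, and the bias acceleration
#' (the `Jdot qdot` term used in the coupled pressure solve).
#'
#' @param model A [dynamics_model()].
#' @param state A `psw_state`.
#' @param points n x 3 matrix of world-space surface points.
#' @param link Character or integer vector of length n naming the link each
#'   point belongs to.
#' @return List with `velocity` (n x 3), `accel_bias` (n x 3) and
#'   `jacobian` (list of 3 x ndof matrices).
#' @export
interface_kinematics <- function(model, state, points, link) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (is.numeric(link)) link <- names(model$links)[link]
  if (!all(link %in% names(model$links)))
    stop("points must be attributed to body links")
  kin <- fk(model, state$x, state$Rb, state$qj)
  L <- link_jacobians(model, kin, state$x)
  mo <- link_motion(model, kin, state$x, state$v, state$om, state$qdj)
  n <- nrow(points)
  vel <- matrix(0, n, 3)
  acc <- matrix(0, n, 3)
  jac <- vector("list", n)
  for (i in seq_len(n)) {
    nm <- link[i]
    d <- points[i, ] - kin[[nm]]$com
    J <- L[[nm]][1:3, , drop = FALSE] - skew3(d) %*% L[[nm]][4:6, , drop = FALSE]
    jac[[i]] <- J
    m <- mo[[nm]]
    vel[i, ] <- m$vcom + cross3(m$omega, d)
    acc[i, ] <- m$acom_bias + cross3(m$alpha_bias, d) +
      cross3(m$omega, cross3(m$omega, d))
  }
  list(velocity = vel, accel_bias = acc, jacobian = jac)
}

#' Total linear momentum, center of mass and mass of the articulated body
#' @param model A [dynamics_model()].
#' @param state A `psw_state`.
#' @return List with `momentum` (kg m/s), `com` (m) and `mass` (kg).
#' @export
body_momentum <- function(model, state) {
  kin <- fk(model, state$x, state$Rb, state$qj)
  mo <- link_motion(model, kin, state$x, state$v, state$om, state$qdj)
  p <- c(0, 0, 0)
  com <- c(0, 0, 0)
  mt <- 0
  for (nm in names(model$links)) {
    m <- model$links[[nm]]$mass
    p <- p + m * mo[[nm]]$vcom
    com <- com + m * kin[[nm]]$com
    mt <- mt + m
  }
  list(momentum = p, com = com / mt, mass = mt)
}
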