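# Variational two-way pressure coupling.
#
# One linear solve produces a pressure field that simultaneously enforces
# fluid incompressibility and drives the articulated body.  Every grid face
# carries a fluid-area fraction w_f computed from the sub-grid voxelization;
# the constraint per fluid cell reads
#
#   sum_faces s dx^2 [ w_f u_f  +  (1 - w_f) m . (J qdot+ + dt Jdot qdot) ] = 0
#
# so that the fluid part of each face moves with the fluid and the covered
# part with the body (a uniformly translating body in a uniformly
# translating fluid is exactly divergence free).  Substituting the updates
# u = u* - dt grad(p)/rho and qdot+ = qdot* + dt M^-1 E^T p gives a
# symmetric positive semi-definite system: a w_f-weighted 7-point Laplacian
# plus the low-rank body term E M^-1 E^T.  The same E (solid-area weighted
# face normals mapped through the link Jacobians) builds the matrix, the
# right-hand side and the generalized pressure force, so action-reaction
# holds structurally.  Faces adjacent to solid-labelled cells carry the
# solid term at full area (their fluid velocity has no pressure neighbor);
# with no body present everything reduces entry-wise to the plain Poisson
# projection.

MIN_FLUID_FRACTION <- 0.01  # cells under this fluid fraction are solid

# effective face weights, pressure-cell mask and coupled-face incidences
interface_faces <- function(vox) {
  n <- vox$grid$n
  dx <- vox$grid$dx
  fluid <- vox$frac >= MIN_FLUID_FRACTION
  wu <- vox$wu; wv <- vox$wv; ww <- vox$ww
  if (is.null(wu)) {  # pure-fluid shortcut
    return(list(fluidmask = array(TRUE, n), inc = NULL,
                wu = array(1, n + c(1, 0, 0)), wv = array(1, n + c(0, 1, 0)),
                ww = array(1, n + c(0, 0, 1))))
  }
  wu_raw <- wu; wv_raw <- wv; ww_raw <- ww
  zero_nonfluid <- function() {
    # no pressure connection across a face unless both cells are fluid
    both <- fluid[1:(n[1] - 1), , ] & fluid[2:n[1], , ]
    wu[2:n[1], , ][!both] <<- 0
    wu[1, , ] <<- 0; wu[n[1] + 1, , ] <<- 0
    both <- fluid[, 1:(n[2] - 1), ] & fluid[, 2:n[2], ]
    wv[, 2:n[2], ][!both] <<- 0
    wv[, 1, ] <<- 0; wv[, n[2] + 1, ] <<- 0
    both <- fluid[, , 1:(n[3] - 1)] & fluid[, , 2:n[3]]
    ww[, , 2:n[3]][!both] <<- 0
    ww[, , 1] <<- 0
    ww[, , n[3] + 1][!fluid[, , n[3]]] <<- 0
  }
  zero_nonfluid()
  # prune fluid cells with no pressure connection at all (isolated slivers)
  for (pass in 1:2) {
    diag <- wu[1:n[1], , ] + wu[2:(n[1] + 1), , ] +
      wv[, 1:n[2], ] + wv[, 2:(n[2] + 1), ] +
      ww[, , 1:n[3]] + ww[, , 2:(n[3] + 1)]
    bad <- fluid & diag <= 0
    if (!any(bad)) break
    fluid[bad] <- FALSE
    zero_nonfluid()
  }

  owner <- vox$owner
  cells <- integer(0); olist <- integer(0); coefs <- numeric(0)
  mlist <- list(); clist <- list()
  ax <- lapply(1:3, function(a) grid_axis(vox$grid, a))
  faceax <- lapply(1:3, function(a) {
    nn <- n[a]
    (seq_len(nn + 1) - 1 - nn / 2) * dx + vox$grid$center[a]
  })
  add_dir <- function(comp, weff, wraw) {
    # interior faces f = 2..n[comp] between cells f-1 and f along comp
    dmi <- dim(weff)
    idx <- as.list(rep(TRUE, 3)); idx[[comp]] <- 2:n[comp]
    wf <- do.call(`[`, c(list(weff), idx, list(drop = FALSE)))
    wr <- do.call(`[`, c(list(wraw), idx, list(drop = FALSE)))
    lo_idx <- as.list(rep(TRUE, 3)); lo_idx[[comp]] <- 1:(n[comp] - 1)
    hi_idx <- as.list(rep(TRUE, 3)); hi_idx[[comp]] <- 2:n[comp]
    flo <- do.call(`[`, c(list(fluid), lo_idx, list(drop = FALSE)))
    fhi <- do.call(`[`, c(list(fluid), hi_idx, list(drop = FALSE)))
    olo <- do.call(`[`, c(list(owner), lo_idx, list(drop = FALSE)))
    ohi <- do.call(`[`, c(list(owner), hi_idx, list(drop = FALSE)))
    cov <- 1 - wf
    sel <- which(cov > 1e-9 & (flo | fhi))
    if (!length(sel)) return(invisible(NULL))
    pos <- arrayInd(sel, dim(wf))     # pos[, comp] = face index - 1
    fpos <- pos; fpos[, comp] <- fpos[, comp] + 1L
    ctr <- cbind(
      if (1 == comp) faceax[[1]][fpos[, 1]] else ax[[1]][fpos[, 1]],
      if (2 == comp) faceax[[2]][fpos[, 2]] else ax[[2]][fpos[, 2]],
      if (3 == comp) faceax[[3]][fpos[, 3]] else ax[[3]][fpos[, 3]])
    own <- ifelse(!fhi[sel] & ohi[sel] > 0, ohi[sel],
                  ifelse(!flo[sel] & olo[sel] > 0, olo[sel],
                         pmax(olo[sel], ohi[sel])))
    own[own == 0] <- 1L
    lo_cell <- pos; hi_cell <- pos; hi_cell[, comp] <- hi_cell[, comp] + 1L
    lo_lin <- lo_cell[, 1] + n[1] * (lo_cell[, 2] - 1 + n[2] * (lo_cell[, 3] - 1))
    hi_lin <- hi_cell[, 1] + n[1] * (hi_cell[, 2] - 1 + n[2] * (hi_cell[, 3] - 1))
    em <- diag(3)[comp, ]
    s1 <- flo[sel]
    if (any(s1)) {
      cells <<- c(cells, lo_lin[s1]); olist <<- c(olist, own[s1])
      coefs <<- c(coefs, cov[sel][s1] * dx^2)
      mlist[[length(mlist) + 1]] <<- matrix(rep(em, each = sum(s1)), ncol = 3)
      clist[[length(clist) + 1]] <<- ctr[s1, , drop = FALSE]
    }
    s2 <- fhi[sel]
    if (any(s2)) {
      cells <<- c(cells, hi_lin[s2]); olist <<- c(olist, own[s2])
      coefs <<- c(coefs, cov[sel][s2] * dx^2)
      mlist[[length(mlist) + 1]] <<- matrix(rep(-em, each = sum(s2)), ncol = 3)
      clist[[length(clist) + 1]] <<- ctr[s2, , drop = FALSE]
    }
    invisible(NULL)
  }
  add_dir(1, wu, wu_raw)
  add_dir(2, wv, wv_raw)
  add_dir(3, ww, ww_raw)
  inc <- if (length(cells)) {
    list(cell = cells, m = do.call(rbind, mlist),
         center = do.call(rbind, clist), owner = olist, w = coefs)
  } else NULL
  list(fluidmask = fluid, inc = inc, wu = wu, wv = wv, ww = ww,
       wu_raw = wu_raw, wv_raw = wv_raw, ww_raw = ww_raw)
}

#' Generalized pressure force on the articulated body
#'
#' Sums the solid-area weighted pressure terms `(1 - w_f) dx^2 J^T p m`
#' over the coupled interface face incidences; this is the same operator E
#' that enters the coupled pressure system (action equals reaction by
#' construction).
#'
#' @param p Pressure array (Pa) over the grid cells.
#' @param vox A [voxelize()] result for the current pose.
#' @param model A [dynamics_model()].
#' @param state The matching `psw_state`.
#' @return Generalized force (ndof-vector).
#' @export
pressure_to_generalized_force <- function(p, vox, model, state) {
  fc <- if (is.null(vox$fluidmask)) interface_faces(vox) else vox
  nd <- model_ndof(model)
  if (is.null(fc$inc)) return(numeric(nd))
  kin <- fk(model, state$x, state$Rb, state$qj)
  L <- link_jacobians(model, kin, state$x)
  f <- fc$inc
  coef <- f$w * as.vector(p)[f$cell]
  tau <- numeric(nd)
  lnames <- names(model$links)
  for (li in seq_along(lnames)) {
    sel <- f$owner == li
    if (!any(sel)) next
    com <- kin[[lnames[li]]]$com
    d <- f$center[sel, , drop = FALSE] - rep(com, each = sum(sel))
    mm <- f$m[sel, , drop = FALSE]
    cf <- coef[sel]
    force <- colSums(cf * mm)
    torque <- colSums(cf * cbind(
      d[, 2] * mm[, 3] - d[, 3] * mm[, 2],
      d[, 3] * mm[, 1] - d[, 1] * mm[, 3],
      d[, 1] * mm[, 2] - d[, 2] * mm[, 1]))
    Jl <- L[[lnames[li]]]
    tau <- tau + as.vector(t(Jl[1:3, , drop = FALSE]) %*% force) +
      as.vector(t(Jl[4:6, , drop = FALSE]) %*% torque)
  }
  tau
}

# world velocity and bias acceleration of interface points, by owner link
face_point_motion <- function(model, kin, mo, inc) {
  n <- nrow(inc$m)
  vel <- matrix(0, n, 3)
  acc <- matrix(0, n, 3)
  lnames <- names(model$links)
  for (li in seq_along(lnames)) {
    sel <- inc$owner == li
    if (!any(sel)) next
    nm <- lnames[li]
    com <- kin[[nm]]$com
    m1 <- mo[[nm]]
    d <- inc$center[sel, , drop = FALSE] - rep(com, each = sum(sel))
    omx <- m1$omega
    wxd <- cbind(omx[2] * d[, 3] - omx[3] * d[, 2],
                 omx[3] * d[, 1] - omx[1] * d[, 3],
                 omx[1] * d[, 2] - omx[2] * d[, 1])
    vel[sel, ] <- rep(m1$vcom, each = sum(sel)) + wxd
    al <- m1$alpha_bias
    acc[sel, ] <- rep(m1$acom_bias, each = sum(sel)) + cbind(
      al[2] * d[, 3] - al[3] * d[, 2],
      al[3] * d[, 1] - al[1] * d[, 3],
      al[1] * d[, 2] - al[2] * d[, 1]) + cbind(
      omx[2] * wxd[, 3] - omx[3] * wxd[, 2],
      omx[3] * wxd[, 1] - omx[1] * wxd[, 3],
      omx[1] * wxd[, 2] - omx[2] * wxd[, 1])
  }
  list(vel = vel, acc = acc)
}

#' Coupled (or pure-fluid) pressure projection
#'
#' Assembles and solves the symmetric positive semi-definite pressure
#' system, applies the velocity correction to the fluid, applies the
#' pressure impulse to the body's generalized velocities, and overwrites
#' body-covered faces with the body's local velocity.
#'
#' @param fl A `psw_mac` state holding the intermediate velocity `u*`.
#' @param vox A [voxelize()] result for the current pose, or `NULL` for
#'   pure fluid.
#' @param model,state Dynamics model and state carrying `qdot*`; `NULL`
#'   for pure fluid.
#' @param dt Time step in seconds.
#' @param couple If `FALSE`, the body motion is prescribed: the solid
#'   velocities enter the right-hand side but receive no pressure impulse
#'   (the immovable/towed-obstacle limit).
#' @param rtol,atol,maxit PCG stopping controls (residual in m^3/s).
#' @return List with updated `fluid`, updated `state` (when coupled),
#'   `tau` (generalized pressure force), `p`, and solver diagnostics.
#' @export
coupled_project <- function(fl, vox, model, state, dt, couple = TRUE,
                            rtol = 1e-10, atol = 0, maxit = 500) {
  n <- fl$grid$n
  dx <- fl$grid$dx
  fc <- if (is.null(vox)) {
    interface_faces(list(grid = fl$grid, frac = array(1, n), wu = NULL))
  } else if (!is.null(vox$fluidmask)) {
    vox
  } else {
    interface_faces(vox)
  }
  fluid <- fc$fluidmask
  inc <- fc$inc

  # weighted intermediate flux divergence
  b <- -cpp_divergence(fl$u * fc$wu, fl$v * fc$wv, fl$w * fc$ww, n, dx) * dx^3

  have_model <- !is.null(model) && !is.null(inc)
  K <- if (is.null(inc)) 0L else length(inc$cell)
  Lmat <- matrix(0, 0, 0); Minv <- matrix(0, 0, 0)
  fcell0 <- integer(0); fwv <- numeric(0)
  fmm <- matrix(0, 0, 3); fdd <- matrix(0, 0, 3); flink0 <- integer(0)
  if (K > 0) {
    if (is.null(model))
      stop("coupled interface present but no dynamics model given")
    kin <- fk(model, state$x, state$Rb, state$qj)
    mo <- link_motion(model, kin, state$x, state$v, state$om, state$qdj)
    pm <- face_point_motion(model, kin, mo, inc)
    sflux <- inc$w * rowSums(inc$m * (pm$vel + dt * pm$acc))
    badd <- tapply(sflux, inc$cell, sum)
    bcells <- as.integer(names(badd))
    b[bcells] <- b[bcells] - as.numeric(badd)
    if (couple) {
      L <- link_jacobians(model, kin, state$x)
      Lmat <- do.call(rbind, L)
      M <- mass_matrix(model, state)
      Minv <- solve(M)
      lnames <- names(model$links)
      coms <- t(vapply(lnames, function(nm) kin[[nm]]$com, numeric(3)))
      fcell0 <- as.integer(inc$cell - 1L)
      fwv <- inc$w
      fmm <- inc$m
      fdd <- inc$center - coms[inc$owner, , drop = FALSE]
      flink0 <- as.integer(inc$owner - 1L)
    }
  }

  sol <- cpp_solve_pressure(n, dx, dt, fl$rho, as.integer(fluid), TRUE,
                            as.vector(b), as.vector(fc$wu), as.vector(fc$wv),
                            as.vector(fc$ww), fcell0, fwv, fmm, fdd, flink0,
                            Lmat, Minv, rtol, atol, as.integer(maxit))
  p <- array(sol$p, n)
  fl$p <- p

  # velocity corrections on connected fluid-fluid faces
  scale <- dt / (fl$rho * dx)
  upd <- fc$wu[2:n[1], , ] > 0
  du <- scale * (p[2:n[1], , ] - p[1:(n[1] - 1), , ])
  fl$u[2:n[1], , ][upd] <- fl$u[2:n[1], , ][upd] - du[upd]
  upd <- fc$wv[, 2:n[2], ] > 0
  dv <- scale * (p[, 2:n[2], ] - p[, 1:(n[2] - 1), ])
  fl$v[, 2:n[2], ][upd] <- fl$v[, 2:n[2], ][upd] - dv[upd]
  upd <- fc$ww[, , 2:n[3]] > 0
  dw <- scale * (p[, , 2:n[3]] - p[, , 1:(n[3] - 1)])
  fl$w[, , 2:n[3]][upd] <- fl$w[, , 2:n[3]][upd] - dw[upd]
  # free surface: Dirichlet p = 0 at the top plane (ghost pressure -p)
  topf <- fc$ww[, , n[3] + 1] > 0
  fl$w[, , n[3] + 1][topf] <- fl$w[, , n[3] + 1][topf] +
    2 * scale * p[, , n[3]][topf]
  fl <- enforce_walls(fl)

  out <- list(fluid = fl, tau = NULL, state = state, p = p,
              iter = sol$iter, resid = sol$resid, n_coupled_faces = K)
  if (K > 0) {
    if (couple) {
      tau <- as.vector(sol$tau)
      gv <- c(state$v, state$om, state$qdj) + dt * as.vector(Minv %*% tau)
      state$v <- gv[1:3]
      state$om <- gv[4:6]
      if (length(gv) > 6) state$qdj <- gv[-(1:6)]
      out$tau <- tau
    } else {
      out$tau <- pressure_to_generalized_force(p, fc, model, state)
    }
    fl <- set_solid_faces(fl, fc, vox, model, state)
    out$fluid <- fl
    out$state <- state
  }
  out
}

# set faces majority-covered by the body (or adjacent to solid cells) to
# the local body velocity, for advection and diagnostics
set_solid_faces <- function(fl, fc, vox, model, state) {
  n <- fl$grid$n
  dx <- fl$grid$dx
  solid <- !fc$fluidmask
  owner <- vox$owner
  owner[owner == 0 & solid] <- 1L
  kin <- fk(model, state$x, state$Rb, state$qj)
  mo <- link_motion(model, kin, state$x, state$v, state$om, state$qdj)
  lnames <- names(model$links)
  vels <- lapply(lnames, function(nm) mo[[nm]])
  coms <- lapply(lnames, function(nm) kin[[nm]]$com)

  set_comp <- function(arr, wraw, comp) {
    dmi <- dim(arr)
    idx_hi <- as.list(rep(TRUE, 3)); idx_hi[[comp]] <- seq_len(n[comp])
    idx_lo <- as.list(rep(TRUE, 3)); idx_lo[[comp]] <- seq_len(n[comp]) + 1L
    ad1 <- array(FALSE, dmi); ow1 <- array(0L, dmi)
    ad1 <- do.call(`[<-`, c(list(ad1), idx_hi, list(solid)))
    ow1 <- do.call(`[<-`, c(list(ow1), idx_hi, list(owner * solid)))
    ad2 <- array(FALSE, dmi); ow2 <- array(0L, dmi)
    ad2 <- do.call(`[<-`, c(list(ad2), idx_lo, list(solid)))
    ow2 <- do.call(`[<-`, c(list(ow2), idx_lo, list(owner * solid)))
    # also faces majority-covered by a thin feature between fluid cells
    cov <- wraw < 0.5
    oany1 <- do.call(`[<-`, c(list(array(0L, dmi)), idx_hi, list(vox$owner)))
    oany2 <- do.call(`[<-`, c(list(array(0L, dmi)), idx_lo, list(vox$owner)))
    adj <- (ad1 | ad2 | cov) & (pmax(ow1, ow2, oany1, oany2) > 0)
    own <- pmax(ow1, ow2)
    own[own == 0] <- pmax(oany1, oany2)[own == 0]
    sel <- which(adj & own > 0)
    if (!length(sel)) return(arr)
    pos <- arrayInd(sel, dmi)
    offs <- c(0.5, 0.5, 0.5); offs[comp] <- 0
    px <- (pos[, 1] - 1 + offs[1] - n[1] / 2) * dx + fl$grid$center[1]
    py <- (pos[, 2] - 1 + offs[2] - n[2] / 2) * dx + fl$grid$center[2]
    pz <- (pos[, 3] - 1 + offs[3] - n[3] / 2) * dx + fl$grid$center[3]
    ow <- own[sel]
    val <- numeric(length(sel))
    for (li in seq_along(lnames)) {
      s2 <- ow == li
      if (!any(s2)) next
      m1 <- vels[[li]]
      com <- coms[[li]]
      d1 <- px[s2] - com[1]; d2 <- py[s2] - com[2]; d3 <- pz[s2] - com[3]
      omx <- m1$omega
      vx <- m1$vcom[1] + omx[2] * d3 - omx[3] * d2
      vy <- m1$vcom[2] + omx[3] * d1 - omx[1] * d3
      vz <- m1$vcom[3] + omx[1] * d2 - omx[2] * d1
      val[s2] <- switch(comp, vx, vy, vz)
    }
    arr[sel] <- val
    arr
  }
  fl$u <- set_comp(fl$u, fc$wu_raw, 1)
  fl$v <- set_comp(fl$v, fc$wv_raw, 2)
  fl$w <- set_comp(fl$w, fc$ww_raw, 3)
  enforce_walls(fl)
}

#' One step of the two-way coupled simulation
#'
#' Step 1 advances fluid (BFECC advection + gravity) and solid (Stable-PD
#' joint torques + gravity) independently; step 2 re-voxelizes the body at
#' its tentative pose, solves the coupled pressure system, corrects the
#' fluid velocities, applies the pressure impulse to the body's
#' generalized velocities and re-integrates its positions with the
#' corrected velocities.
#'
#' @param fl A `psw_mac` fluid state.
#' @param model A [dynamics_model()].
#' @param state A `psw_state`.
#' @param targets Function of time returning the anatomical joint targets
#'   in degrees (as [joint_targets()]), or `NULL` for a passive body.
#' @param dt Time step in seconds.
#' @param subres Voxelization sub-grid resolution.
#' @param gravity How gravity is treated.  `"balanced"` (default) solves
#'   for dynamic pressure: gravity on the fluid and the hydrostatic
#'   pressure gradient cancel analytically, and the body feels only the
#'   net of weight and Archimedes buoyancy per link (exactly zero at
#'   neutral density), which keeps a resting neutrally buoyant body
#'   exactly at rest.  `"explicit"` applies `g` to fluid and body and lets
#'   the pressure solve supply buoyancy discretely; `"off"` disables
#'   gravity entirely.
#' @param couple If `FALSE` the body follows its prescribed motion and
#'   receives no pressure impulse.
#' @param scheme Advection scheme.
#' @param rtol PCG relative tolerance for the per-step pressure solve.
#' @return List with updated `fluid`, `state`, the voxelization, and
#'   solver diagnostics.
#' @export
coupled_step <- function(fl, model, state, targets = NULL, dt = 0.01,
                         subres = 3, gravity = c("balanced", "explicit",
                                                 "off"),
                         couple = TRUE, scheme = "bfecc", rtol = 1e-7) {
  gravity <- match.arg(gravity)
  # step 1a: fluid
  fl <- advect_velocity(fl, dt, scheme = scheme)
  if (gravity == "explicit") fl <- apply_gravity(fl, dt)
  # step 1b: solid under internal + gravity torques only
  old <- state
  nj <- length(model$pivots) * 3
  if (!is.null(targets) && nj > 0) {
    t2 <- state$t + dt
    tgt <- anatomical_to_frame(model, targets(t2))
    tgtd <- (anatomical_to_frame(model, targets(t2 + 1e-4)) - tgt) / 1e-4
    tau <- spd_torques(model, state, tgt, tgtd, dt)
  } else {
    tau <- numeric(model_ndof(model))
  }
  if (gravity == "explicit")
    tau <- tau + gravity_force(model, state, fl$g)
  if (gravity == "balanced")
    tau <- tau + gravity_buoyancy_force(model, state, fl$rho, fl$g)
  st1 <- integrate_state(model, state, tau, dt,
                         implicit_damping = !is.null(targets) && nj > 0)
  # step 2: voxelize at the tentative pose, solve, correct
  kin <- fk(model, st1$x, st1$Rb, st1$qj)
  vox <- voxelize(model$body, fk_pose(kin), fl$grid, subres)
  cp <- coupled_project(fl, vox, model, st1, dt, couple = couple,
                        rtol = rtol)
  st2 <- cp$state
  if (couple) {
    # re-integrate positions from the pre-step state with corrected rates
    st2$x <- old$x + dt * st2$v
    st2$Rb <- orthonormalize(exp_so3(st2$om * dt) %*% old$Rb)
    st2$qj <- old$qj + dt * st2$qdj
  }
  list(fluid = cp$fluid, state = st2, vox = vox, p = cp$p, iter = cp$iter,
       resid = cp$resid, n_coupled_faces = cp$n_coupled_faces,
       tau = cp$tau)
}

# build a closure applying the coupled pressure operator (for tests)
make_coupled_operator <- function(grid, vox, model = NULL, state = NULL,
                                  dt = 0.01, rho = 1000) {
  fc <- if (is.null(vox)) {
    interface_faces(list(grid = grid, frac = array(1, grid$n), wu = NULL))
  } else if (!is.null(vox$fluidmask)) vox else interface_faces(vox)
  inc <- fc$inc
  n <- grid$n
  if (!is.null(inc) && !is.null(model)) {
    kin <- fk(model, state$x, state$Rb, state$qj)
    L <- link_jacobians(model, kin, state$x)
    Lmat <- do.call(rbind, L)
    Minv <- solve(mass_matrix(model, state))
    lnames <- names(model$links)
    coms <- t(vapply(lnames, function(nm) kin[[nm]]$com, numeric(3)))
    fcell0 <- as.integer(inc$cell - 1L)
    fwv <- inc$w
    fmm <- inc$m
    fdd <- inc$center - coms[inc$owner, , drop = FALSE]
    flink0 <- as.integer(inc$owner - 1L)
  } else {
    fcell0 <- integer(0); fwv <- numeric(0)
    fmm <- matrix(0, 0, 3); fdd <- matrix(0, 0, 3); flink0 <- integer(0)
    Lmat <- matrix(0, 0, 0); Minv <- matrix(0, 0, 0)
  }
  function(p) {
    cpp_apply_coupled_operator(n, grid$dx, dt, rho,
                               as.integer(fc$fluidmask), TRUE,
                               as.vector(fc$wu), as.vector(fc$wv),
                               as.vector(fc$ww), fcell0, fwv, fmm, fdd,
                               flink0, Lmat, Minv, as.vector(p))
  }
}
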