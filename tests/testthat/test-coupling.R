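# Two-way variational pressure coupling.

test_that("with no solid the coupled operator reduces to the pure Poisson operator", {
  g <- make_grid(c(10, 10, 10), domain = c(1, 1, 1))
  A <- plesioswim:::make_coupled_operator(g, NULL, dt = 0.01)
  # reference 7-point Laplacian with top Dirichlet, assembled in R
  n <- g$n
  s0 <- 0.01 * g$dx / 1000
  ref <- function(p) {
    p <- array(p, n)
    out <- array(0, n)
    for (d in 1:3) {
      lo <- as.list(rep(TRUE, 3)); lo[[d]] <- 1:(n[d] - 1)
      hi <- as.list(rep(TRUE, 3)); hi[[d]] <- 2:n[d]
      plo <- do.call(`[`, c(list(p), lo, list(drop = FALSE)))
      phi <- do.call(`[`, c(list(p), hi, list(drop = FALSE)))
      dif <- plo - phi
      out <- out + do.call(`[<-`, c(list(array(0, n)), lo, list(dif)))
      out <- out - do.call(`[<-`, c(list(array(0, n)), hi, list(dif)))
    }
    out[, , n[3]] <- out[, , n[3]] + 2 * p[, , n[3]]
    s0 * as.vector(out)
  }
  set.seed(8)
  for (i in 1:3) {
    p <- rnorm(prod(n))
    expect_equal(A(p), ref(p), tolerance = 1e-12)
  }
})

test_that("the coupled operator stays symmetric PSD with a submerged box", {
  g <- make_grid(c(16, 16, 16), domain = c(1, 1, 1))
  body <- rigid_body(box_mesh(0.3, 0.25, 0.2), density = 1000)
  model <- dynamics_model(body)
  st <- init_state(x = c(0.5, 0, 0.5), qj = numeric(0))
  kin <- plesioswim:::fk(model, st$x, st$Rb, st$qj)
  vox <- voxelize(body, plesioswim:::fk_pose(kin), g, subres = 3)
  A <- plesioswim:::make_coupled_operator(g, vox, model, st, dt = 0.01)
  set.seed(9)
  quad_min <- Inf
  nrmA <- 0
  for (i in 1:8) {
    u <- rnorm(prod(g$n)); v <- rnorm(prod(g$n))
    Au <- A(u)
    expect_equal(sum(v * Au), sum(u * A(v)), tolerance = 1e-9)
    quad_min <- min(quad_min, sum(u * Au) / sum(u * u))
    nrmA <- max(nrmA, sqrt(sum(Au^2) / sum(u^2)))
  }
  expect_gte(quad_min, -1e-10 * nrmA)
})

test_that("zero pressure gives zero generalized force", {
  fx <- fix_sphere_vox48()
  tau <- pressure_to_generalized_force(array(0, fx$grid$n), fx$vox,
                                       fx$model, fx$state)
  expect_equal(tau, numeric(6))
})

test_that("uniform pressure on a closed body yields (near) zero net force", {
  fx <- fix_sphere_vox48()
  pc <- 5000
  tau <- pressure_to_generalized_force(array(pc, fx$grid$n), fx$vox,
                                       fx$model, fx$state)
  A <- pi * 0.35^2
  expect_lt(max(abs(tau[1:3])) / (pc * A), 0.02)
})

test_that("hydrostatic pressure reproduces Archimedes buoyancy within 5%", {
  fx <- fix_sphere_vox48()
  ax <- plesioswim:::grid_axis(fx$grid, 3)
  p <- array(0, fx$grid$n)
  for (k in seq_len(fx$grid$n[3]))
    p[, , k] <- 1000 * 9.81 * (fx$grid$domain[3] - ax[k])
  tau <- pressure_to_generalized_force(p, fx$vox, fx$model, fx$state)
  B_ref <- 1000 * 9.81 * mesh_volume(fix_sphere())
  expect_equal(tau[3], B_ref, tolerance = 0.05)
  expect_lt(max(abs(tau[1:2])), 0.01 * B_ref)
})

test_that("a neutrally buoyant sphere at rest stays at rest", {
  fx <- fix_sphere_rest()
  expect_lt(sqrt(sum((fx$state$x - fx$x0)^2)), 1e-3)
  expect_lt(sqrt(sum(fx$state$v^2)), 1e-4)
})

test_that("pressure impulse on the body equals E^T p (action-reaction)", {
  g <- make_grid(c(24, 24, 24), domain = c(2, 2, 2))
  body <- rigid_body(fix_sphere(), density = 1000)
  model <- dynamics_model(body)
  st <- init_state(x = c(1, 0, 1), qj = numeric(0))
  st$v <- c(0.4, 0.1, -0.2)   # moving sphere forces a nontrivial solve
  fl <- mac_state(g)
  kin <- plesioswim:::fk(model, st$x, st$Rb, st$qj)
  vox <- voxelize(body, plesioswim:::fk_pose(kin), g, subres = 3)
  cp <- plesioswim:::coupled_project(fl, vox, model, st, dt = 0.01)
  tau_R <- pressure_to_generalized_force(cp$p, vox, model, st)
  expect_equal(cp$tau, tau_R, tolerance = 1e-9)
  expect_gt(sqrt(sum(cp$tau^2)), 1)   # the check is not vacuous
})

test_that("fluid faces at a towed box match its normal velocity in the weighted sense", {
  g <- make_grid(c(32, 32, 32), domain = c(2, 2, 2))
  body <- rigid_body(box_mesh(0.66, 0.66, 0.66), density = 1000)
  model <- dynamics_model(body)
  st <- init_state(x = c(1, 0, 1), qj = numeric(0))
  st$v <- c(0.5, 0, 0)
  fl <- mac_state(g)
  kin <- plesioswim:::fk(model, st$x, st$Rb, st$qj)
  vox <- voxelize(body, plesioswim:::fk_pose(kin), g, subres = 3)
  fc <- plesioswim:::interface_faces(vox)
  cp <- plesioswim:::coupled_project(fl, vox, model, st, dt = 0.01,
                                     couple = FALSE)
  # weighted flux balance at interface cells: the fluid-area flux must
  # cancel the solid-area flux, i.e. the fluid moves with the box's normal
  # velocity in the volume-fraction-weighted sense
  inc <- fc$inc
  sol_flux <- as.vector(inc$w * (inc$m %*% c(0.5, 0, 0)))
  cells <- sort(unique(inc$cell))
  div_w <- as.vector(plesioswim:::cpp_divergence(
    cp$fluid$u * fc$wu, cp$fluid$v * fc$wv, cp$fluid$w * fc$ww,
    g$n, g$dx)) * g$dx^3
  net <- div_w[cells] +
    as.vector(tapply(sol_flux, inc$cell, sum)[as.character(cells)])
  expect_lt(sum(abs(net)), 0.05 * sum(abs(sol_flux)))
})

test_that("sub-grid fractions improve the added-mass force on an accelerating sphere", {
  # impulsively accelerated sphere in still fluid: pressure reaction is the
  # potential-flow added mass, F = -(rho V / 2) a
  g <- make_grid(c(32, 32, 32), domain = c(2, 2, 2))
  body <- rigid_body(fix_sphere(), density = 1000)
  model <- dynamics_model(body)
  a <- 1.0
  dt <- 0.01
  err <- numeric(2)
  for (si in 1:2) {
    subres <- c(1, 3)[si]
    st <- init_state(x = c(1, 0, 1), qj = numeric(0))
    st$v <- c(a * dt, 0, 0)
    fl <- mac_state(g)
    kin <- plesioswim:::fk(model, st$x, st$Rb, st$qj)
    vox <- voxelize(body, plesioswim:::fk_pose(kin), g, subres = subres)
    cp <- plesioswim:::coupled_project(fl, vox, model, st, dt = dt,
                                       couple = FALSE)
    Fx <- cp$tau[1]
    F_ref <- -0.5 * 1000 * mesh_volume(fix_sphere()) * a
    err[si] <- abs(Fx - F_ref) / abs(F_ref)
  }
  expect_lte(err[2], err[1])
})

test_that("a static body in still water produces no spurious thrust", {
  cfg <- sim_config("mini", dt = 0.025, n_cycles = 2)
  traj <- fix_neutral_sim()
  n <- nrow(traj$track)
  v_end <- (as.numeric(traj$track[n, c("x", "y", "z")]) -
            as.numeric(traj$track[n - 4, c("x", "y", "z")])) /
    (traj$track$t[n] - traj$track$t[n - 4])
  expect_lt(sqrt(sum(v_end^2)), 1e-3)
})
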