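# MAC-grid fluid state and the pure-fluid operations: BFECC advection,
# gravity, and the pressure projection (the coupled projection lives in
# coupling.R; with no solid present it reduces to the plain Poisson solve
# used here).
#
# Boundary layout: solid (no-penetration) walls on the four sides and the
# bottom, free surface (p = 0) at the top plane.  The swimmer starts deep
# enough that surface effects stay small.

#' Create a still MAC fluid state
#'
#' @param grid A [make_grid()].
#' @param rho Fluid density, kg/m^3.
#' @param gravity Gravitational acceleration 3-vector, m/s^2.
#' @return A `psw_mac` list with face-velocity arrays `u`, `v`, `w`
#'   (staggered), the grid, and physical constants.
#' @export
mac_state <- function(grid, rho = 1000, gravity = c(0, 0, -9.81)) {
  n <- grid$n
  structure(list(
    grid = grid, rho = rho, g = gravity,
    u = array(0, c(n[1] + 1, n[2], n[3])),
    v = array(0, c(n[1], n[2] + 1, n[3])),
    w = array(0, c(n[1], n[2], n[3] + 1)),
    p = array(0, n)), class = "psw_mac")
}

# zero the wall-normal boundary faces (sides and bottom; the top face is
# the free surface and may carry velocity)
enforce_walls <- function(fl) {
  n <- fl$grid$n
  fl$u[1, , ] <- 0
  fl$u[n[1] + 1, , ] <- 0
  fl$v[, 1, ] <- 0
  fl$v[, n[2] + 1, ] <- 0
  fl$w[, , 1] <- 0
  fl
}

#' Self-advect the MAC velocity field
#'
#' BFECC (back and forth error compensation and correction) built from
#' semi-Lagrangian sweeps with RK2 back-traces; the corrected result is
#' clamped to the local sample bounds of the input field.  If the CFL
#' number `max|u| dt / dx` exceeds `cfl`, the advection is sub-stepped.
#'
#' @param fl A `psw_mac` state.
#' @param dt Time step in seconds.
#' @param scheme "bfecc" or "sl" (plain semi-Lagrangian).
#' @param cfl Maximum CFL number per sub-step.
#' @return Updated state.
#' @export
advect_velocity <- function(fl, dt, scheme = c("bfecc", "sl"), cfl = 0.9) {
  scheme <- match.arg(scheme)
  vmax <- max(abs(range(fl$u)), abs(range(fl$v)), abs(range(fl$w)))
  nsub <- max(1L, ceiling(vmax * dt / (cfl * fl$grid$dx)))
  sdt <- dt / nsub
  for (s in seq_len(nsub)) {
    res <- cpp_advect_velocity(fl$u, fl$v, fl$w, fl$grid$n, fl$grid$dx, sdt,
                               scheme == "bfecc")
    fl$u <- array(res$u, dim(fl$u))
    fl$v <- array(res$v, dim(fl$v))
    fl$w <- array(res$w, dim(fl$w))
  }
  enforce_walls(fl)
}

#' Advect a cell-centered scalar field through the MAC velocity
#'
#' @param fl A `psw_mac` state.
#' @param field nx x ny x nz array.
#' @param dt Time step in seconds.
#' @param scheme "bfecc" or "sl".
#' @return Advected array.
#' @export
advect_scalar <- function(fl, field, dt, scheme = c("bfecc", "sl")) {
  scheme <- match.arg(scheme)
  out <- cpp_advect_scalar(as.vector(field), fl$u, fl$v, fl$w, fl$grid$n,
                           fl$grid$dx, dt, scheme == "bfecc")
  array(out, fl$grid$n)
}

#' Apply gravity to the fluid (explicit Euler)
#'
#' Increments the vertical face velocities by `g dt` (bottom wall faces
#' stay zero).
#'
#' @param fl A `psw_mac` state.
#' @param dt Time step in seconds.
#' @return Updated state.
#' @export
apply_gravity <- function(fl, dt) {
  nz <- fl$grid$n[3]
  fl$w[, , 2:(nz + 1)] <- fl$w[, , 2:(nz + 1)] + fl$g[3] * dt
  if (any(fl$g[1:2] != 0)) {
    fl$u[2:fl$grid$n[1], , ] <- fl$u[2:fl$grid$n[1], , ] + fl$g[1] * dt
    fl$v[, 2:fl$grid$n[2], ] <- fl$v[, 2:fl$grid$n[2], ] + fl$g[2] * dt
  }
  fl
}

#' Discrete divergence of the MAC velocity
#'
#' @param fl A `psw_mac` state.
#' @return nx x ny x nz array in 1/s.
#' @export
divergence <- function(fl) {
  array(cpp_divergence(fl$u, fl$v, fl$w, fl$grid$n, fl$grid$dx), fl$grid$n)
}

#' Pure-fluid pressure projection
#'
#' Solves the Poisson equation for pressure with Neumann conditions at the
#' walls and a Dirichlet `p = 0` free surface at the top plane, then
#' subtracts `dt grad(p) / rho` from the face velocities.  This is the
#' no-solid reduction of the coupled projection.
#'
#' @param fl A `psw_mac` state.
#' @param dt Time step in seconds.
#' @param rtol,atol,maxit PCG stopping controls (residual in outflow units).
#' @return Updated state with pressure field in `fl$p` (Pa) and solver
#'   diagnostics in `fl$solve`.
#' @export
project_pure_fluid <- function(fl, dt = 0.01, rtol = 1e-10, atol = 0,
                               maxit = 500) {
  coupled_project(fl, vox = NULL, model = NULL, state = NULL, dt = dt,
                  rtol = rtol, atol = atol, maxit = maxit)$fluid
}
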