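# Shared fixtures, generated once per test run and cached in-process.

.psw_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .psw_cache)) {
    assign(name, force(expr), envir = .psw_cache)
  }
  get(name, envir = .psw_cache)
}

fix_sphere <- function() cached("sphere", uv_sphere(0.35, nthet = 40, nphi = 80))

fix_body <- function() cached("body", build_swimmer(body_spec()))

fix_body_mini <- function() {
  cached("body_mini",
         build_swimmer(body_spec(min_thickness = make_grid(c(20, 16, 12))$dx)))
}

fix_model <- function() cached("model", dynamics_model(fix_body()))

fix_preset <- function() cached("preset", joint_presets("medium"))

# an asymmetric but valid flapping stroke used across tests
fix_stroke <- function() {
  cached("stroke", {
    v <- c(-38, 25, 0.0, -20, 0, 0.25, -35, 25, 0.25, 0.62, 0.5, 0.6, 0.5,
           -45, 12, 0.0, -48, -10, 0.25, -35, 25, 0.25, 0.62, 0.5, 0.6, 0.5)
    decode_stroke(v, fix_preset(), warn = FALSE)
  })
}

# voxelization of the sphere at 48^3 over a 2 m box (shared by the
# Archimedes and uniform-pressure checks)
fix_sphere_vox48 <- function() {
  cached("sphere_vox48", {
    g <- make_grid(c(48, 48, 48), domain = c(2, 2, 2))
    body <- rigid_body(fix_sphere())
    model <- dynamics_model(body)
    st <- init_state(x = c(1, 0, 1), qj = numeric(0))
    kin <- plesioswim:::fk(model, st$x, st$Rb, st$qj)
    vox <- voxelize(body, plesioswim:::fk_pose(kin), g, subres = 3)
    list(grid = g, body = body, model = model, state = st, vox = vox)
  })
}

# short zero-amplitude swim at the mini grid (no thrust reference);
# started at the stroke pose so the limbs genuinely never move
fix_neutral_sim <- function() {
  cached("neutral_sim", {
    cfg <- sim_config("mini", dt = 0.025, n_cycles = 2)
    st0 <- joint_targets(neutral_stroke(fix_preset()), 0, "all", fix_preset())
    run_simulation(fix_body_mini(), neutral_stroke(fix_preset()),
                   fix_preset(), "all", cfg, start_pose_deg = st0)
  })
}

# neutrally buoyant sphere resting in still water for 2 s (32^3)
fix_sphere_rest <- function() {
  cached("sphere_rest", {
    g <- make_grid(c(32, 32, 32), domain = c(2, 2, 2))
    body <- rigid_body(fix_sphere(), density = 1000)
    model <- dynamics_model(body)
    st <- init_state(x = c(1, 0, 1), qj = numeric(0))
    fl <- mac_state(g)
    x0 <- st$x
    for (i in 1:200) {
      res <- coupled_step(fl, model, st, NULL, dt = 0.01, subres = 3)
      fl <- res$fluid
      st <- res$state
    }
    list(state = st, x0 = x0)
  })
}
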