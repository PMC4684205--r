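# Procedural swimmer geometry: a rigid torso (head + neck + trunk + tail as
# one watertight mesh) and four cambered hydrofoil flippers.  Proportions
# emulate a 3.35 m Meyerasaurus-like plesiosaur: a moderately long neck,
# high-aspect-ratio subequal fore and hind flippers, and a short tail.
#
# Frames: the body (torso) frame has x anterior, y left, z up, origin at the
# torso center of mass.  Each flipper mesh is built in its joint frame with
# the span along +y (left side); right-side flippers are exact sagittal
# mirrors.  The thinnest features are kept at or above the minimum feature
# thickness resolvable by the fluid grid (67 mm at the reference cell size).

#' Specification of the procedural swimmer body
#'
#' @param total_length Head-to-tail length in meters.
#' @param muscle_bulk_factor 1 for the slim model; 1.5 adds 50% more soft
#'   tissue volume around the bases of the limbs.
#' @param min_thickness Minimum feature thickness in meters (thin features
#'   such as flipper trailing edges are thickened to this floor so the
#'   fluid grid can resolve them).
#' @param n_axial,n_ring Torso mesh resolution (stations along the axis,
#'   points around each section).
#' @param n_span,n_chord Flipper mesh resolution.
#' @return A `psw_body_spec` list; pass to [build_swimmer()].
#' @export
body_spec <- function(total_length = 3.35, muscle_bulk_factor = 1,
                      min_thickness = 0.067, n_axial = 56, n_ring = 24,
                      n_span = 16, n_chord = 16) {
  stopifnot(total_length > 0, muscle_bulk_factor >= 1, min_thickness > 0)
  L <- total_length
  structure(list(
    total_length = L,
    muscle_bulk_factor = muscle_bulk_factor,
    min_thickness = min_thickness,
    n_axial = n_axial, n_ring = n_ring,
    n_span = n_span, n_chord = n_chord,
    # torso half-width / half-height profiles (fraction of length from nose,
    # meters); smooth spline through anatomical control points
    profile_u = c(0.00, 0.04, 0.10, 0.16, 0.24, 0.32, 0.38, 0.46, 0.54,
                  0.62, 0.68, 0.76, 0.84, 0.92, 1.00),
    half_width = c(0.010, 0.065, 0.085, 0.068, 0.062, 0.075, 0.150, 0.270,
                   0.300, 0.270, 0.200, 0.120, 0.070, 0.035, 0.008),
    half_height = c(0.010, 0.055, 0.072, 0.060, 0.055, 0.068, 0.130, 0.215,
                    0.240, 0.215, 0.165, 0.105, 0.068, 0.040, 0.008),
    section_exponent = 2.3,
    # limb placement (fraction of length from nose) and planform (meters)
    u_shoulder = 0.40, u_hip = 0.665,
    fore_span = 0.78, fore_root_chord = 0.34,
    hind_span = 0.72, hind_root_chord = 0.32,
    flipper_camber = 0.035,   # camber as fraction of chord
    flipper_sweep = 0.12,     # posterior tip offset in meters at full span
    pivot_drop = 0.05         # pivot placed slightly ventral of mid-height
  ), class = "psw_body_spec")
}

# compact-support bump used for muscle-bulk modification: 1 at s=0, exactly
# 0 for s >= 1 (keeps the distal flipper planform bit-identical)
bulk_bump <- function(s) ifelse(s < 1, (1 - s^2)^2, 0)

# torso profile evaluators (with muscle-bulk bumps at shoulder and hip)
torso_profiles <- function(spec) {
  fw <- splinefun(spec$profile_u, spec$half_width, method = "natural")
  fh <- splinefun(spec$profile_u, spec$half_height, method = "natural")
  bulk <- spec$muscle_bulk_factor - 1
  half_min <- spec$min_thickness / 2
  wfun <- function(u) {
    b <- 1 + 0.45 * bulk * (bulk_bump(abs(u - spec$u_shoulder) / 0.10) +
                            bulk_bump(abs(u - spec$u_hip) / 0.10))
    pmax(fw(u) * b, half_min)
  }
  hfun <- function(u) {
    b <- 1 + 0.45 * bulk * (bulk_bump(abs(u - spec$u_shoulder) / 0.10) +
                            bulk_bump(abs(u - spec$u_hip) / 0.10))
    pmax(fh(u) * b, half_min)
  }
  list(w = wfun, h = hfun)
}

# build the torso mesh in a frame with origin at mid-length (shifted to the
# COM later); nose at +x
build_torso <- function(spec) {
  L <- spec$total_length
  prof <- torso_profiles(spec)
  u <- seq(0, 1, length.out = spec$n_axial + 1)
  # cluster stations near the ends for smoother tips
  u <- (1 - cos(pi * u)) / 2
  x <- (0.5 - u) * L
  th <- seq(0, 2 * pi, length.out = spec$n_ring + 1)[seq_len(spec$n_ring)]
  e <- spec$section_exponent
  sgnpow <- function(v, p) sign(v) * abs(v)^p
  cy <- sgnpow(cos(th), 2 / e)
  sz <- sgnpow(sin(th), 2 / e)
  inner <- 2:spec$n_axial
  rings <- lapply(inner, function(i) {
    cbind(rep(x[i], spec$n_ring), prof$w(u[i]) * cy, prof$h(u[i]) * sz)
  })
  V <- rbind(c(x[1], 0, 0), do.call(rbind, rings),
             c(x[length(x)], 0, 0))
  nr <- length(inner)
  np <- spec$n_ring
  ring_idx <- function(r) 1 + (r - 1) * np + seq_len(np)
  tris <- list()
  r1 <- ring_idx(1)
  tris[[1]] <- cbind(1, r1, c(r1[-1], r1[1]))
  for (r in seq_len(nr - 1)) {
    ra <- ring_idx(r); rb <- ring_idx(r + 1)
    ran <- c(ra[-1], ra[1]); rbn <- c(rb[-1], rb[1])
    tris[[length(tris) + 1]] <- cbind(ra, rb, rbn)
    tris[[length(tris) + 1]] <- cbind(ra, rbn, ran)
  }
  last <- nrow(V)
  rl <- ring_idx(nr)
  tris[[length(tris) + 1]] <- cbind(last, c(rl[-1], rl[1]), rl)
  m <- mesh(V, do.call(rbind, tris))
  if (mesh_volume(m) < 0) m$triangles <- m$triangles[, c(1, 3, 2)]
  m
}

# cambered hydrofoil flipper in its joint frame: span along +y, chord along
# -x (leading edge anterior), thickness along z.  `root_bulk` > 0 thickens
# the proximal half only.
build_flipper <- function(span, root_chord, camber_frac, sweep, min_thick,
                          root_bulk, n_span, n_chord) {
  s <- seq(0, 1, length.out = n_span + 1)
  s <- s[-(n_span + 1)]            # tip handled by cap point
  chord <- root_chord * (0.30 + 0.70 * sqrt(pmax(0, 1 - s^2)))
  thick <- pmax(min_thick, 0.16 * chord * (1 - 0.35 * s)) *
    (1 + 0.5 * root_bulk * bulk_bump(s / 0.5))
  chord <- chord * (1 + 0.25 * root_bulk * bulk_bump(s / 0.5))
  xoff <- -sweep * s^1.5           # posterior sweep of the leading edge
  xi <- seq(0, 1, length.out = n_chord + 1)[-c(1, n_chord + 1)]
  shape <- sqrt(pmax(0, 4 * xi * (1 - xi)))   # rounded LE/TE plate section
  rings <- lapply(seq_along(s), function(i) {
    xc <- xoff[i] + 0.30 * chord[i] - xi * chord[i]
    zc <- camber_frac * chord[i] * sin(pi * xi)
    up <- cbind(xc, s[i] * span, zc + 0.5 * thick[i] * shape)
    lo <- cbind(rev(xc), s[i] * span, rev(zc) - 0.5 * rev(thick[i] * shape))
    le <- c(xoff[i] + 0.30 * chord[i], s[i] * span, 0)
    te <- c(xoff[i] - 0.70 * chord[i], s[i] * span, 0)
    rbind(le, up, te, lo)
  })
  np <- nrow(rings[[1]])
  V <- do.call(rbind, rings)
  tip <- c(xoff[length(s)] - 0.2 * chord[length(s)], span, 0)
  V <- rbind(c(mean(rings[[1]][, 1]), 0, 0), V, tip)
  nr <- length(s)
  ring_idx <- function(r) 1 + (r - 1) * np + seq_len(np)
  tris <- list()
  r1 <- ring_idx(1)
  tris[[1]] <- cbind(1, c(r1[-1], r1[1]), r1)       # root cap (faces -y)
  for (r in seq_len(nr - 1)) {
    ra <- ring_idx(r); rb <- ring_idx(r + 1)
    ran <- c(ra[-1], ra[1]); rbn <- c(rb[-1], rb[1])
    tris[[length(tris) + 1]] <- cbind(ra, rbn, rb)
    tris[[length(tris) + 1]] <- cbind(ra, ran, rbn)
  }
  last <- nrow(V)
  rl <- ring_idx(nr)
  tris[[length(tris) + 1]] <- cbind(last, rl, c(rl[-1], rl[1]))
  m <- mesh(V, do.call(rbind, tris))
  if (mesh_volume(m) < 0) m$triangles <- m$triangles[, c(1, 3, 2)]
  m
}

#' Build the articulated swimmer from a body specification
#'
#' Returns the five rigid links (one torso including head, neck and tail;
#' four flippers), their mass properties at uniform density 1000 kg/m^3
#' (neutral buoyancy), and the joint pivots.  Right-side flippers are exact
#' sagittal mirrors of the left ones.
#'
#' @param spec A [body_spec()].
#' @param density Uniform body density, kg/m^3.
#' @return A `psw_body` list with elements `links` (named list of meshes in
#'   link frames), `props` (per-link mass/COM/inertia), `pivots` (joint
#'   pivot positions in the body frame), `side` (+1 left / -1 right per
#'   joint) and `spec`.
#' @export
build_swimmer <- function(spec = body_spec(), density = 1000) {
  torso <- build_torso(spec)
  tp <- mesh_mass_props(torso, density)
  # shift torso frame origin to torso COM
  torso <- mesh_transform(torso, t = -tp$com)
  prof <- torso_profiles(spec)
  L <- spec$total_length
  x_sh <- (0.5 - spec$u_shoulder) * L - tp$com[1]
  x_hp <- (0.5 - spec$u_hip) * L - tp$com[1]
  y_sh <- prof$w(spec$u_shoulder) * 0.92
  y_hp <- prof$w(spec$u_hip) * 0.92
  z_sh <- -spec$pivot_drop * prof$h(spec$u_shoulder) / 0.24 * 0.24
  z_hp <- -spec$pivot_drop * prof$h(spec$u_hip) / 0.24 * 0.24
  root_bulk <- spec$muscle_bulk_factor - 1
  fore <- build_flipper(spec$fore_span, spec$fore_root_chord,
                        spec$flipper_camber, spec$flipper_sweep,
                        spec$min_thickness, root_bulk,
                        spec$n_span, spec$n_chord)
  hind <- build_flipper(spec$hind_span, spec$hind_root_chord,
                        spec$flipper_camber, spec$flipper_sweep,
                        spec$min_thickness, root_bulk,
                        spec$n_span, spec$n_chord)
  links <- list(
    torso = torso,
    fore_left = fore,
    fore_right = mesh_mirror_y(fore),
    hind_left = hind,
    hind_right = mesh_mirror_y(hind))
  for (nm in names(links)) {
    if (!is_watertight(links[[nm]]))
      stop("generated link mesh is not watertight: ", nm)
    if (mesh_volume(links[[nm]]) <= 0)
      stop("generated link mesh has non-positive volume: ", nm)
  }
  props <- lapply(links, mesh_mass_props, density = density)
  props$torso$com <- c(0, 0, 0)  # by construction
  pivots <- list(
    fore_left = c(x_sh, y_sh, z_sh),
    fore_right = c(x_sh, -y_sh, z_sh),
    hind_left = c(x_hp, y_hp, z_hp),
    hind_right = c(x_hp, -y_hp, z_hp))
  structure(list(links = links, props = props, pivots = pivots,
                 side = c(fore_left = 1, fore_right = -1,
                          hind_left = 1, hind_right = -1),
                 density = density, spec = spec),
            class = "psw_body")
}

#' @export
print.psw_body <- function(x, ...) {
  vols <- vapply(x$links, mesh_volume, 0)
  cat(sprintf("psw_body: 5 links, total volume %.3f m^3, mass %.1f kg\n",
              sum(vols), sum(vols) * x$density))
  ext <- body_extent(x)
  cat(sprintf("  axial extent %.3f m, muscle bulk factor %.2f\n",
              ext, x$spec$muscle_bulk_factor))
  invisible(x)
}

#' Axial (head-to-tail) extent of the torso mesh
#' @param body A `psw_body`.
#' @return Length in meters.
#' @export
body_extent <- function(body) {
  diff(range(body$links$torso$vertices[, 1]))
}
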