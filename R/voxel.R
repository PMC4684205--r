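# Regular fluid grid definition, voxelization of the posed body onto it,
# and sub-grid fluid volume fractions.

#' Define a regular fluid grid
#'
#' The reference configuration is 100 x 80 x 60 cells over a
#' 6.6 x 5.28 x 3.96 m^3 region of water (cell size 0.066 m); the desk
#' configuration halves the resolution over the same domain.  The grid is
#' centered laterally at y = 0 so a sagittally symmetric body voxelizes
#' symmetrically.
#'
#' @param n Integer 3-vector of cell counts (nx, ny, nz).
#' @param domain Numeric 3-vector of physical extents in meters.
#' @param center Domain center; default puts y = 0 at mid-width with the
#'   x and z corners at 0.
#' @return A `psw_grid` list with `n`, `dx`, `center`, `origin`.
#' @export
make_grid <- function(n = c(100, 80, 60), domain = c(6.6, 5.28, 3.96),
                      center = c(domain[1] / 2, 0, domain[3] / 2)) {
  n <- as.integer(n)
  dx <- domain[1] / n[1]
  stopifnot(abs(domain[2] / n[2] - dx) < 1e-9 * dx,
            abs(domain[3] / n[3] - dx) < 1e-9 * dx)
  structure(list(n = n, dx = dx, domain = domain, center = center,
                 origin = center - domain / 2),
            class = "psw_grid")
}

#' Named grid scales
#'
#' `paper` is the full 100x80x60 reference grid (about an hour per
#' simulated stroke pair on one core); `desk` is 50x40x30; `coarse` is
#' 25x20x15 and is used for the fast optimization tier and tests.
#'
#' @param scale One of "paper", "desk", "coarse".
#' @return A `psw_grid`.
#' @export
grid_scale <- function(scale = c("desk", "paper", "coarse")) {
  scale <- match.arg(scale)
  n <- switch(scale, paper = c(100, 80, 60), desk = c(50, 40, 30),
              coarse = c(25, 20, 15))
  make_grid(n)
}

# cell center coordinates along one axis (exactly antisymmetric about the
# domain center)
grid_axis <- function(grid, axis, sub = 1) {
  n <- grid$n[axis] * sub
  h <- grid$dx / sub
  (seq_len(n) - 0.5 - n / 2) * h + grid$center[axis]
}

# world-space vertex lists of the posed body (list of meshes + transforms)
posed_vertices <- function(body, pose) {
  lapply(names(body$links), function(nm) {
    V <- body$links[[nm]]$vertices
    V %*% t(pose[[nm]]$R) + rep(pose[[nm]]$t, each = nrow(V))
  })
}

check_in_domain <- function(body, pose, grid) {
  lo <- grid$origin
  hi <- grid$origin + grid$domain
  for (nm in names(body$links)) {
    V <- body$links[[nm]]$vertices %*% t(pose[[nm]]$R)
    V <- V + rep(pose[[nm]]$t, each = nrow(V))
    if (any(V[, 1] < lo[1]) || any(V[, 1] > hi[1]) ||
        any(V[, 2] < lo[2]) || any(V[, 2] > hi[2]) ||
        any(V[, 3] < lo[3]) || any(V[, 3] > hi[3]))
      stop("link leaves the fluid domain: ", nm)
  }
  invisible(TRUE)
}

#' Voxelize a posed body onto a grid
#'
#' Marks every cell whose center lies inside any posed link mesh as solid,
#' and computes per-cell fluid volume fractions from `subres^3` sub-cell
#' inside/outside parity tests (1/27 precision at the default 3x3x3).
#'
#' @param body A `psw_body` (or a single `psw_mesh`).
#' @param pose Named list per link of `R` (3x3) and `t` (3-vector) world
#'   transforms, as produced by the dynamics module; `NULL` poses a single
#'   mesh at identity.
#' @param grid A `psw_grid`.
#' @param subres Sub-grid resolution per axis (default 3).
#' @return A `psw_voxels` list: `labels` (nx x ny x nz array, 1 = solid
#'   center), `frac` (fluid volume fraction array), `owner` (1-based link
#'   index owning each solid cell center, 0 elsewhere), `grid`, `subres`.
#' @export
voxelize <- function(body, pose = NULL, grid = grid_scale("desk"),
                     subres = 3) {
  stopifnot(subres >= 1)
  if (inherits(body, "psw_mesh")) {
    Vs <- list(body$vertices)
    Fs <- list(body$triangles)
    if (!is.null(pose)) {
      Vs[[1]] <- Vs[[1]] %*% t(pose$R) + rep(pose$t, each = nrow(Vs[[1]]))
    }
  } else {
    stopifnot(inherits(body, "psw_body"), !is.null(pose))
    check_in_domain(body, pose, grid)
    Vs <- posed_vertices(body, pose)
    Fs <- lapply(body$links, `[[`, "triangles")
  }
  res <- cpp_voxelize_links(Vs, unname(Fs), grid$n, grid$dx, grid$center,
                            as.integer(subres))
  if (res$failures > 0)
    warning(res$failures, " voxel columns kept degenerate ray hits")
  n <- grid$n
  structure(list(
    labels = array(res$labels, n),
    frac = array(res$frac, n),
    owner = array(res$owner, n),
    wu = array(res$wu, n + c(1, 0, 0)),
    wv = array(res$wv, n + c(0, 1, 0)),
    ww = array(res$ww, n + c(0, 0, 1)),
    grid = grid, subres = subres),
    class = "psw_voxels")
}

#' Fluid volume fractions of a posed body
#'
#' Convenience wrapper around [voxelize()] returning only the fraction
#' field; at `subres = 1` the fractions are the binary cell labels.
#'
#' @inheritParams voxelize
#' @return nx x ny x nz array of fluid volume fractions in `[0, 1]`.
#' @export
volume_fractions <- function(body, pose = NULL, grid = grid_scale("desk"),
                             subres = 3) {
  voxelize(body, pose, grid, subres)$frac
}

#' Export grid fields to a legacy-ASCII VTK structured-points file
#'
#' @param grid A `psw_grid`.
#' @param fields Named list of cell arrays (nx x ny x nz) or MAC velocity
#'   (a list with u, v, w face arrays, written cell-averaged as a vector
#'   field).
#' @param path Output path.
#' @export
write_vtk <- function(grid, fields, path) {
  n <- grid$n
  lines <- c("# vtk DataFile Version 3.0", "plesioswim fields", "ASCII",
             "DATASET STRUCTURED_POINTS",
             sprintf("DIMENSIONS %d %d %d", n[1], n[2], n[3]),
             sprintf("ORIGIN %g %g %g", grid$origin[1] + grid$dx / 2,
                     grid$origin[2] + grid$dx / 2,
                     grid$origin[3] + grid$dx / 2),
             sprintf("SPACING %g %g %g", grid$dx, grid$dx, grid$dx),
             sprintf("POINT_DATA %d", prod(n)))
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (is.list(f)) {  # MAC velocity: average faces to centers
      nx <- n[1]; ny <- n[2]; nz <- n[3]
      uc <- (f$u[1:nx, , , drop = FALSE] + f$u[2:(nx + 1), , , drop = FALSE]) / 2
      vc <- (f$v[, 1:ny, , drop = FALSE] + f$v[, 2:(ny + 1), , drop = FALSE]) / 2
      wc <- (f$w[, , 1:nz, drop = FALSE] + f$w[, , 2:(nz + 1), drop = FALSE]) / 2
      lines <- c(lines, sprintf("VECTORS %s float", nm),
                 paste(as.vector(uc), as.vector(vc), as.vector(wc)))
    } else {
      lines <- c(lines, sprintf("SCALARS %s float 1", nm),
                 "LOOKUP_TABLE default",
                 paste(as.vector(f)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
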