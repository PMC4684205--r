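# Triangle meshes: construction helpers, watertightness checks, mass
# properties by signed tetrahedron decomposition, OBJ/STL input and output.

#' Create a triangle mesh
#'
#' A mesh is a list with `vertices` (n x 3 matrix, meters) and `triangles`
#' (m x 3 integer matrix of 1-based vertex indices, consistently oriented
#' with outward normals).
#'
#' @param vertices n x 3 numeric matrix.
#' @param triangles m x 3 integer matrix.
#' @return An object of class `psw_mesh`.
#' @export
mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  storage.mode(triangles) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3,
            max(triangles) <= nrow(vertices), min(triangles) >= 1)
  structure(list(vertices = vertices, triangles = as.matrix(triangles)),
            class = "psw_mesh")
}

#' @export
print.psw_mesh <- function(x, ...) {
  cat(sprintf("psw_mesh: %d vertices, %d triangles, volume %.4f m^3\n",
              nrow(x$vertices), nrow(x$triangles), mesh_volume(x)))
  invisible(x)
}

#' Check that every edge of a mesh is shared by exactly two triangles
#'
#' Also requires consistent orientation: each directed edge must appear
#' exactly once.
#'
#' @param m A `psw_mesh`.
#' @return `TRUE` if watertight and consistently oriented.
#' @export
is_watertight <- function(m) {
  tr <- m$triangles
  he <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  keys <- paste(he[, 1], he[, 2])
  if (any(duplicated(keys))) return(FALSE)
  rkeys <- paste(he[, 2], he[, 1])
  all(rkeys %in% keys)
}

# signed volume/COM/inertia of a closed mesh by tetrahedra against origin
mesh_moments <- function(m) {
  V <- m$vertices
  Tr <- m$triangles
  a <- V[Tr[, 1], , drop = FALSE]
  b <- V[Tr[, 2], , drop = FALSE]
  c_ <- V[Tr[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  detv <- rowSums(a * cr)                       # 6 * signed tet volume
  vol <- sum(detv) / 6
  ctd <- colSums(detv * (a + b + c_)) / 4 / 6   # volume-weighted centroid sum
  com <- ctd / vol
  # second moments over signed tets (0,a,b,c):
  # Int x_p x_q dV = detv/120 * sum_i v_i[p] * (v_1[q]+v_2[q]+v_3[q]+v_i[q])
  pr <- function(p, q) {
    s <- a[, p] * (2 * a[, q] + b[, q] + c_[, q]) +
         b[, p] * (a[, q] + 2 * b[, q] + c_[, q]) +
         c_[, p] * (a[, q] + b[, q] + 2 * c_[, q])
    sum(detv * s) / 120
  }
  Ixx <- pr(2, 2) + pr(3, 3)
  Iyy <- pr(1, 1) + pr(3, 3)
  Izz <- pr(1, 1) + pr(2, 2)
  Ixy <- -pr(1, 2)
  Ixz <- -pr(1, 3)
  Iyz <- -pr(2, 3)
  I0 <- matrix(c(Ixx, Ixy, Ixz, Ixy, Iyy, Iyz, Ixz, Iyz, Izz), 3, 3)
  # shift to COM (parallel axis, unit density)
  r2 <- sum(com^2)
  Ic <- I0 - vol * (r2 * diag(3) - outer(com, com))
  list(volume = vol, com = com, inertia_unit_density = Ic)
}

#' Enclosed volume of a watertight mesh (divergence theorem)
#' @param m A `psw_mesh`.
#' @return Volume in cubic meters (positive for outward orientation).
#' @export
mesh_volume <- function(m) mesh_moments(m)$volume

#' Mass properties of a uniform-density watertight mesh
#'
#' @param m A `psw_mesh`.
#' @param density Density in kg/m^3 (default 1000, neutral buoyancy in water).
#' @return List with `mass`, `com` (3-vector) and `inertia` (3x3 about COM).
#' @export
mesh_mass_props <- function(m, density = 1000) {
  mo <- mesh_moments(m)
  list(mass = density * mo$volume, com = mo$com,
       inertia = density * mo$inertia_unit_density,
       volume = mo$volume)
}

#' Test whether points lie inside a watertight mesh
#'
#' Casts an axis-aligned ray from each point and classifies by intersection
#' parity; rays that graze an edge or vertex are re-cast with a
#' deterministic sequence of slightly rotated directions.
#'
#' @param m A `psw_mesh` (must be watertight).
#' @param points 3-vector or n x 3 matrix of query points.
#' @param axis Ray direction axis, 1 (x), 2 (y) or 3 (z).
#' @return Logical vector.
#' @export
point_inside <- function(m, points, axis = 1) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(axis %in% 1:3)
  cpp_points_inside(m$vertices, m$triangles, as.matrix(points),
                    as.integer(axis - 1))
}

# rigid transform of a mesh
mesh_transform <- function(m, R = diag(3), t = c(0, 0, 0)) {
  mesh(m$vertices %*% t(R) + rep(t, each = nrow(m$vertices)), m$triangles)
}

# mirror a mesh about the y = 0 plane (flips winding to keep outward normals)
mesh_mirror_y <- function(m) {
  V <- m$vertices
  V[, 2] <- -V[, 2]
  mesh(V, m$triangles[, c(1, 3, 2)])
}

#' Write a mesh to a Wavefront OBJ file
#' @param m A `psw_mesh`.
#' @param path Output file path.
#' @export
write_obj <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", m$vertices[, 1], m$vertices[, 2],
                     m$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", m$triangles[, 1], m$triangles[, 2],
                     m$triangles[, 3]), con)
  invisible(path)
}

#' Read a triangle mesh from a Wavefront OBJ file
#' @param path Input file path.
#' @return A `psw_mesh`. Faces with more than 3 vertices are fan-triangulated.
#' @export
read_obj <- function(path) {
  ln <- readLines(path)
  vln <- ln[startsWith(ln, "v ")]
  fln <- ln[startsWith(ln, "f ")]
  V <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vln)), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  faces <- lapply(strsplit(trimws(sub("^f", "", fln)), "\\s+"), function(x) {
    idx <- as.integer(sub("/.*", "", x))
    if (length(idx) == 3) return(matrix(idx, 1, 3))
    do.call(rbind, lapply(2:(length(idx) - 1),
                          function(i) c(idx[1], idx[i], idx[i + 1])))
  })
  mesh(V, do.call(rbind, faces))
}

#' Write a mesh to an ASCII STL file
#' @param m A `psw_mesh`.
#' @param path Output file path.
#' @param name Solid name stored in the file.
#' @export
write_stl <- function(m, path, name = "psw") {
  V <- m$vertices
  Tr <- m$triangles
  a <- V[Tr[, 1], , drop = FALSE]
  b <- V[Tr[, 2], , drop = FALSE]
  c_ <- V[Tr[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / pmax(len, 1e-30)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", name), con)
  chunk <- sprintf(
    "facet normal %.9g %.9g %.9g\n outer loop\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n endloop\nendfacet",
    nrm[, 1], nrm[, 2], nrm[, 3], a[, 1], a[, 2], a[, 3],
    b[, 1], b[, 2], b[, 3], c_[, 1], c_[, 2], c_[, 3])
  writeLines(chunk, con)
  writeLines(paste("endsolid", name), con)
  invisible(path)
}

#' Read an ASCII STL file
#' @param path Input file path.
#' @return A `psw_mesh` (vertices merged exactly).
#' @export
read_stl <- function(path) {
  ln <- trimws(readLines(path))
  vln <- ln[startsWith(ln, "vertex")]
  V <- do.call(rbind, lapply(strsplit(sub("^vertex\\s+", "", vln), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  key <- paste(V[, 1], V[, 2], V[, 3])
  uk <- !duplicated(key)
  map <- match(key, key[uk])
  Vu <- V[uk, , drop = FALSE]
  Tr <- matrix(map, ncol = 3, byrow = TRUE)
  mesh(Vu, Tr)
}

#' Latitude-longitude sphere mesh
#'
#' Watertight triangulated sphere, used as an analytic oracle in tests.
#'
#' @param radius,center Sphere geometry.
#' @param nthet,nphi Tessellation (latitude bands, longitude steps).
#' @return A `psw_mesh`.
#' @export
uv_sphere <- function(radius = 1, center = c(0, 0, 0), nthet = 32, nphi = 64) {
  th <- seq(0, pi, length.out = nthet + 1)[2:nthet]  # exclude poles
  ph <- seq(0, 2 * pi, length.out = nphi + 1)[1:nphi]
  ringv <- lapply(th, function(t)
    cbind(sin(t) * cos(ph), sin(t) * sin(ph), rep(cos(t), nphi)))
  V <- rbind(c(0, 0, 1), do.call(rbind, ringv), c(0, 0, -1))
  V <- V * radius + rep(center, each = nrow(V))
  nr <- length(th)
  tris <- list()
  top <- 1
  ring <- function(r) 1 + (r - 1) * nphi + seq_len(nphi)
  r1 <- ring(1)
  tris[[1]] <- cbind(top, r1, c(r1[-1], r1[1]))
  for (r in seq_len(nr - 1)) {
    ra <- ring(r); rb <- ring(r + 1)
    ran <- c(ra[-1], ra[1]); rbn <- c(rb[-1], rb[1])
    tris[[length(tris) + 1]] <- cbind(ra, rb, rbn)
    tris[[length(tris) + 1]] <- cbind(ra, rbn, ran)
  }
  bot <- nrow(V)
  rl <- ring(nr)
  tris[[length(tris) + 1]] <- cbind(bot, c(rl[-1], rl[1]), rl)
  m <- mesh(V, do.call(rbind, tris))
  if (mesh_volume(m) < 0) m$triangles <- m$triangles[, c(1, 3, 2)]
  m
}

#' Axis-aligned box mesh
#'
#' @param lx,ly,lz Edge lengths in meters.
#' @param center Box center.
#' @return A watertight `psw_mesh` with outward-oriented triangles.
#' @export
box_mesh <- function(lx, ly, lz, center = c(0, 0, 0)) {
  hx <- lx / 2; hy <- ly / 2; hz <- lz / 2
  V <- as.matrix(expand.grid(x = c(-hx, hx), y = c(-hy, hy), z = c(-hz, hz)))
  dimnames(V) <- NULL
  V <- V + rep(center, each = 8)
  # vertices ordered (x fastest): index = 1 + ix + 2*iy + 4*iz
  Tr <- rbind(
    c(1, 3, 7), c(1, 7, 5),    # x- face
    c(2, 8, 4), c(2, 6, 8),    # x+ face
    c(1, 5, 6), c(1, 6, 2),    # y- face
    c(3, 4, 8), c(3, 8, 7),    # y+ face
    c(1, 4, 3), c(1, 2, 4),    # z- face
    c(5, 7, 8), c(5, 8, 6))    # z+ face
  m <- mesh(V, Tr)
  if (mesh_volume(m) < 0) m$triangles <- m$triangles[, c(1, 3, 2)]
  m
}
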