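# Procedural body generation, inside/outside queries, voxelization and
# sub-grid volume fractions.

test_that("generated swimmer links are watertight with correct dimensions", {
  body <- fix_body()
  for (nm in names(body$links)) {
    expect_true(is_watertight(body$links[[nm]]))
    expect_gt(mesh_volume(body$links[[nm]]), 0)
  }
  expect_equal(body_extent(body), 3.35, tolerance = 1e-9)
  # left/right flippers are exact sagittal mirrors
  fl <- body$links$fore_left$vertices
  fr <- body$links$fore_right$vertices
  expect_identical(fr[, 2], -fl[, 2])
  expect_identical(fr[, c(1, 3)], fl[, c(1, 3)])
})

test_that("muscle-bulk variant grows torso and limb bases but not the distal planform", {
  slim <- fix_body()
  bulk <- cached("bulk_body",
                 build_swimmer(body_spec(muscle_bulk_factor = 1.5)))
  expect_gt(mesh_volume(bulk$links$torso), mesh_volume(slim$links$torso))
  expect_gt(mesh_volume(bulk$links$fore_left),
            mesh_volume(slim$links$fore_left))
  # distal half of the flipper planform is untouched by the bulk bump
  distal <- function(b) {
    V <- b$links$fore_left$vertices
    V[V[, 2] > 0.6 * max(V[, 2]), ]
  }
  expect_identical(distal(bulk), distal(slim))
})

test_that("thin features are floored at the minimum resolvable thickness", {
  mt <- 0.2
  body <- build_swimmer(body_spec(min_thickness = mt))
  V <- body$links$fore_left$vertices
  # thickness along z at mid-span
  mid <- abs(V[, 2] - 0.5 * max(V[, 2])) < 0.1
  expect_gte(diff(range(V[mid, 3])), mt * 0.95)
})

test_that("point_inside matches the analytic sphere and is ray-direction invariant", {
  s <- fix_sphere()
  set.seed(42)
  P <- matrix(runif(3 * 50000, -0.6, 0.6), ncol = 3)
  truth <- rowSums(P^2) < 0.35^2
  inside <- point_inside(s, P)
  expect_gte(mean(inside == truth), 0.999)
  # far outside and centroid
  expect_false(point_inside(s, c(10, 10, 10)))
  expect_true(point_inside(s, c(0, 0, 0)))
  # three ray directions agree
  P2 <- P[seq_len(2000), ]
  i1 <- point_inside(s, P2, axis = 1)
  i2 <- point_inside(s, P2, axis = 2)
  i3 <- point_inside(s, P2, axis = 3)
  expect_identical(i1, i2)
  expect_identical(i1, i3)
})

test_that("voxelized sphere volume converges to the analytic volume", {
  # r / dx = 8.4 at 48 cells over 2 m
  fx <- fix_sphere_vox48()
  vol_solid <- sum(1 - fx$vox$frac) * fx$grid$dx^3
  expect_equal(vol_solid, 4 / 3 * pi * 0.35^3, tolerance = 0.05)
  # labels: solid iff center inside (spot-check against point_inside)
  idx <- which(fx$vox$labels == 1)
  expect_gt(length(idx), 100)
  pos <- arrayInd(idx[seq(1, length(idx), by = 37)], fx$grid$n)
  ax <- lapply(1:3, function(a) plesioswim:::grid_axis(fx$grid, a))
  pts <- cbind(ax[[1]][pos[, 1]], ax[[2]][pos[, 2]], ax[[3]][pos[, 3]])
  ctr <- sweep(pts, 2, c(1, 0, 1))
  expect_true(all(rowSums(ctr^2) < 0.35^2))
})

test_that("empty domain voxelizes to pure fluid", {
  g <- make_grid(c(8, 8, 8), domain = c(1, 1, 1))
  tiny <- uv_sphere(0.01, center = c(0.5, 0, 0.5), nthet = 8, nphi = 12)
  vox <- voxelize(tiny, NULL, g, subres = 1)
  expect_true(all(vox$labels == 0))
  expect_true(all(vox$frac == 1))
})

test_that("fractions are multiples of 1/27 and half-space matches brute force", {
  fx <- fix_sphere_vox48()
  k27 <- fx$vox$frac * 27
  expect_lt(max(abs(k27 - round(k27))), 1e-12)

  # axis-aligned slab whose boundary lies strictly between sub-cell planes
  g <- make_grid(c(6, 6, 6), domain = c(1, 1, 1))
  z0 <- 0.5 - 0.7 * (g$dx / 3)   # inside a sub-cell layer
  # slab kept narrower than the ray start margin so rays begin outside
  slab <- box_mesh(1.2, 2, z0 + 1, center = c(0.5, 0, (z0 - 1) / 2))
  vox <- voxelize(slab, NULL, g, subres = 3)
  # brute-force oracle: count of sub-cell centers below z0
  sub_z <- plesioswim:::grid_axis(g, 3, sub = 3)
  frac_col <- vapply(seq_len(6), function(ci) {
    zc <- sub_z[(ci - 1) * 3 + 1:3]
    sum(zc > z0) / 3
  }, 0)
  for (ci in seq_len(6))
    expect_equal(unname(vox$frac[3, 3, ci]), frac_col[ci] * 1)
  expect_true(all(vox$frac %in% c(0, 9 / 27, 18 / 27, 1)))
})

test_that("fractions at subres 1 equal binary voxel labels", {
  g <- make_grid(c(24, 24, 24), domain = c(2, 2, 2))
  s <- fix_sphere()
  vox <- voxelize(s, list(R = diag(3), t = c(1, 0, 1)), g, subres = 1)
  expect_identical(as.vector(vox$frac), as.vector(1 - vox$labels))
})

test_that("a sagittally mirrored mesh voxelizes to the exact mirror", {
  g <- make_grid(c(16, 16, 16), domain = c(2, 2, 2))
  # an irregular, asymmetric blob: offset scaled sphere
  s <- uv_sphere(0.3, nthet = 16, nphi = 24)
  s$vertices <- s$vertices %*% diag(c(1.3, 0.8, 1.1))
  s$vertices <- s$vertices + rep(c(1.05, 0.23, 0.97), each = nrow(s$vertices))
  sm <- plesioswim:::mesh_mirror_y(s)
  v1 <- voxelize(s, NULL, g, subres = 3)
  v2 <- voxelize(sm, NULL, g, subres = 3)
  expect_identical(v2$frac, v1$frac[, 16:1, ])
  expect_identical(v2$labels, v1$labels[, 16:1, ])
})

test_that("voxelize refuses a body outside the domain", {
  g <- make_grid(c(10, 10, 10), domain = c(1, 1, 1))
  body <- fix_body()
  pose <- lapply(body$links, function(l) list(R = diag(3), t = c(0.5, 0, 0.5)))
  expect_error(voxelize(body, pose, g), "leaves the fluid domain")
})

test_that("OBJ and STL round-trips preserve the mesh", {
  m <- uv_sphere(0.5, nthet = 8, nphi = 12)
  fo <- tempfile(fileext = ".obj")
  write_obj(m, fo)
  m2 <- read_obj(fo)
  expect_equal(m2$vertices, unname(m$vertices), tolerance = 1e-7)
  expect_identical(dim(m2$triangles), dim(m$triangles))
  fs <- tempfile(fileext = ".stl")
  write_stl(m, fs)
  m3 <- read_stl(fs)
  expect_true(is_watertight(m3))
  expect_equal(mesh_volume(m3), mesh_volume(m), tolerance = 1e-6)
})

test_that("mesh mass properties match closed forms", {
  b <- box_mesh(1, 2, 3, center = c(0.4, -0.2, 0.1))
  mp <- mesh_mass_props(b, 1000)
  expect_equal(mp$mass, 6000, tolerance = 1e-12)
  expect_equal(mp$com, c(0.4, -0.2, 0.1), tolerance = 1e-12)
  expect_equal(diag(mp$inertia), 6000 / 12 * c(4 + 9, 1 + 9, 1 + 4),
               tolerance = 1e-10)
  s <- uv_sphere(0.5, nthet = 64, nphi = 128)
  expect_equal(mesh_volume(s), 4 / 3 * pi * 0.125, tolerance = 2e-3)
})

test_that("VTK export writes a parseable structured-points file", {
  g <- make_grid(c(4, 4, 4), domain = c(1, 1, 1))
  f <- tempfile(fileext = ".vtk")
  write_vtk(g, list(phi = array(seq_len(64), c(4, 4, 4))), f)
  ln <- readLines(f)
  expect_true(any(grepl("STRUCTURED_POINTS", ln)))
  expect_true(any(grepl("SCALARS phi", ln)))
  expect_equal(sum(grepl("^POINT_DATA", ln)), 1)
})
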