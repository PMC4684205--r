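# Small rotation helpers.  World frame: x anterior (initial heading),
# y to the animal's left, z up.  Angles in radians internally.

rot_x <- function(a) {
  c1 <- cos(a); s1 <- sin(a)
  matrix(c(1, 0, 0, 0, c1, s1, 0, -s1, c1), 3, 3)
}

rot_y <- function(a) {
  c1 <- cos(a); s1 <- sin(a)
  matrix(c(c1, 0, -s1, 0, 1, 0, s1, 0, c1), 3, 3)
}

rot_z <- function(a) {
  c1 <- cos(a); s1 <- sin(a)
  matrix(c(c1, s1, 0, -s1, c1, 0, 0, 0, 1), 3, 3)
}

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# exponential map so(3) -> SO(3)
exp_so3 <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3) + skew3(v))
  K <- skew3(v / th)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# geodesic angle between two rotations
rot_angle <- function(R1, R2) {
  ctheta <- (sum(diag(crossprod(R1, R2))) - 1) / 2
  acos(max(-1, min(1, ctheta)))
}

# re-orthonormalize a drifting rotation matrix (Gram-Schmidt)
orthonormalize <- function(R) {
  x <- R[, 1]; x <- x / sqrt(sum(x^2))
  y <- R[, 2] - sum(R[, 2] * x) * x; y <- y / sqrt(sum(y^2))
  z <- cross3(x, y)
  cbind(x, y, z, deparse.level = 0)
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi
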