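# Independent 3x3 rotation-matrix oracle. Everything here is built from
# Rodrigues' formula and plain matrix algebra -- no quaternions -- so it can
# brute-force-check the quaternion path.

o_deg <- pi / 180

# Rodrigues rotation matrix about unit axis u by theta degrees
o_rot <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  th <- theta * o_deg
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# matrix for an intrinsic Z-X'-Y'' Euler triple (x, y, z) in degrees
o_euler_mat <- function(e) {
  o_rot(c(0, 0, 1), e[3]) %*% o_rot(c(1, 0, 0), e[1]) %*% o_rot(c(0, 1, 0), e[2])
}

# Z-X'-Y'' decomposition of a rotation matrix (degrees); same tie-break as
# the package: at lock z = 0, residual on y
o_mat_euler <- function(m) {
  sx <- min(1, max(-1, m[3, 2]))
  if (abs(sx) > 1 - 1e-9) {
    c(asin(sx), atan2(m[1, 3], m[1, 1]), 0) / o_deg
  } else {
    c(asin(sx), atan2(-m[3, 1], m[3, 3]), atan2(-m[1, 2], m[2, 2])) / o_deg
  }
}

# geodesic angle (degrees) between two rotation matrices; atan2 form stays
# well-conditioned for the near-identity differences being measured
o_mat_angle <- function(a, b) {
  r <- t(a) %*% b
  s <- sqrt(sum(c(r[3, 2] - r[2, 3], r[1, 3] - r[3, 1], r[2, 1] - r[1, 2])^2)) / 2
  c_ <- (sum(diag(r)) - 1) / 2
  atan2(s, c_) / o_deg
}

# random rotation as (unit axis, angle); returns list(axis, theta, m)
o_random_rot <- function() {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, -179, 179)
  list(axis = ax, theta = th, m = o_rot(ax, th))
}

# quaternion equality up to the q/-q sign ambiguity
expect_quat_equal <- function(a, b, tol = 1e-9) {
  a <- as.numeric(a); b <- as.numeric(b)
  d <- min(max(abs(a - b)), max(abs(a + b)))
  expect_lt(d, tol)
}
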