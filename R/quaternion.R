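# Unit-quaternion algebra with one fixed Euler convention.
#
# Conventions used throughout the package:
#   * scalar-first component order (w, x, y, z), matching the wire names
#     wq/xq/yq/zq of the packet dialect;
#   * degrees at every public boundary, radians only inside;
#   * Euler decomposition is intrinsic Z-X'-Y'' (rotation matrix
#     R = Rz(z) %*% Rx(x) %*% Ry(y)), the order used by the display engine
#     the original system streamed into;
#   * outputs are canonicalized to w >= 0 (q and -q are the same rotation).

.DEG <- pi / 180

#' Construct a unit quaternion
#'
#' Quaternions are stored scalar-first as a named numeric vector
#' `(w, x, y, z)`. Construction renormalizes when the norm is further than
#' `1e-6` from 1 and rejects near-zero input.
#'
#' @param w,x,y,z numeric components; `w` is the real (scalar) part.
#' @param canonical if `TRUE` (default), flip sign so that `w >= 0`.
#' @return object of class `"quat"`.
#' @examples
#' quat(1, 0, 0, 0)                  # identity rotation
#' quat_from_axis_angle(c(0, 0, 1), 90)
#' @export
quat <- function(w, x, y, z, canonical = TRUE) {
  q <- c(w = as.numeric(w), x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  if (!all(is.finite(q))) stop("quaternion components must be finite")
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("zero quaternion has no rotation interpretation")
  # renormalize only outside tolerance so already-unit components (e.g. from
  # a parsed packet) pass through bit-exactly
  if (abs(n - 1) > 1e-12) q <- q / n
  class(q) <- "quat"
  if (canonical) q <- quat_canonical(q)
  q
}

#' @export
print.quat <- function(x, ...) {
  cat(sprintf("<quat> w=%.6f x=%.6f y=%.6f z=%.6f\n", x[1], x[2], x[3], x[4]))
  invisible(x)
}

#' Identity rotation
#' @return the quaternion `(1, 0, 0, 0)`.
#' @export
quat_identity <- function() quat(1, 0, 0, 0)

#' Canonicalize quaternion sign
#'
#' `q` and `-q` encode the same rotation; for deterministic output the
#' representative with `w >= 0` is used (when `w == 0`, the first non-zero
#' imaginary component is made positive).
#'
#' @param q a `"quat"`.
#' @return the canonical representative.
#' @export
quat_canonical <- function(q) {
  v <- unclass(q)
  nz <- which(v != 0)
  if (length(nz) && v[nz[1]] < 0) v <- -v
  class(v) <- "quat"
  v
}

.as_quat <- function(q) {
  if (inherits(q, "quat")) return(q)
  if (is.numeric(q) && length(q) == 4) return(quat(q[1], q[2], q[3], q[4]))
  stop("expected a quaternion (class 'quat' or numeric length 4)")
}

#' Axis-angle rotation description
#'
#' @param axis unit 3-vector; rejected if its norm is further than `1e-9`
#'   from 1 unless `normalize = TRUE`.
#' @param theta rotation angle in degrees.
#' @param normalize normalize a non-unit axis instead of rejecting it.
#' @return object of class `"axis_angle"` with fields `axis` and `theta`.
#' @export
axis_angle <- function(axis, theta, normalize = FALSE) {
  axis <- as.numeric(axis)
  if (length(axis) != 3 || !all(is.finite(axis))) stop("axis must be a finite 3-vector")
  if (!is.finite(theta)) stop("theta must be finite")
  n <- sqrt(sum(axis^2))
  if (normalize) {
    if (n < 1e-12) stop("cannot normalize a zero axis")
    axis <- axis / n
  } else if (abs(n - 1) > 1e-9) {
    stop("axis must be unit length (norm within 1e-9 of 1)")
  }
  structure(list(axis = axis, theta = as.numeric(theta)), class = "axis_angle")
}

#' Quaternion from an axis-angle rotation
#'
#' A rotation of `theta` degrees about unit axis `u` maps to
#' `cos(theta/2) + (ux i + uy j + uz k) sin(theta/2)`.
#'
#' @param axis an `"axis_angle"` object, or a unit 3-vector when `theta`
#'   is supplied separately.
#' @param theta rotation angle in degrees (ignored when `axis` is an
#'   `"axis_angle"`).
#' @return a `"quat"`.
#' @export
quat_from_axis_angle <- function(axis, theta = NULL) {
  if (inherits(axis, "axis_angle")) {
    aa <- axis
  } else {
    aa <- axis_angle(axis, theta)
  }
  h <- aa$theta * .DEG / 2
  quat(cos(h), aa$axis[1] * sin(h), aa$axis[2] * sin(h), aa$axis[3] * sin(h))
}

#' Hamilton product of two quaternions
#'
#' `quat_multiply(a, b)` composes the rotations "apply `b`, then `a`"
#' (the usual convention when rotations act on column vectors).
#'
#' @param a,b unit quaternions.
#' @return a `"quat"`.
#' @export
quat_multiply <- function(a, b) {
  a <- .as_quat(a); b <- .as_quat(b)
  quat(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

#' Inverse rotation
#'
#' For unit quaternions the inverse is the conjugate:
#' `quat_multiply(q, quat_inverse(q))` is the identity.
#'
#' @param q a unit quaternion.
#' @return a `"quat"`.
#' @export
quat_inverse <- function(q) {
  q <- .as_quat(q)
  quat(q[1], -q[2], -q[3], -q[4])
}

#' Rotate a 3-vector by a quaternion
#'
#' @param q a unit quaternion.
#' @param v numeric 3-vector.
#' @return the rotated 3-vector (norm preserved).
#' @export
quat_rotate <- function(q, v) {
  q <- .as_quat(q)
  v <- as.numeric(v)
  if (length(v) != 3 || !all(is.finite(v))) stop("v must be a finite 3-vector")
  # q v q*  expanded (Rodrigues-style), avoiding two full products
  w <- q[1]; u <- q[2:4]
  uv <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
  uuv <- c(u[2] * uv[3] - u[3] * uv[2], u[3] * uv[1] - u[1] * uv[3], u[1] * uv[2] - u[2] * uv[1])
  unname(v + 2 * (w * uv + uuv))
}

#' Rotation matrix of a quaternion
#'
#' 3x3 orthonormal matrix acting on column vectors; mostly used internally
#' for the Euler decomposition.
#'
#' @param q a unit quaternion.
#' @return 3x3 numeric matrix.
#' @export
quat_to_matrix <- function(q) {
  q <- .as_quat(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Euler angle triple
#'
#' Angles in degrees under the package-wide intrinsic Z-X'-Y'' order; each
#' component is wrapped into `[-180, 180)`.
#'
#' @param x,y,z angles in degrees (finite).
#' @return named numeric of class `"euler"`.
#' @export
euler_triple <- function(x, y, z) {
  e <- c(x = wrap_angle(x), y = wrap_angle(y), z = wrap_angle(z))
  class(e) <- "euler"
  e
}

#' @export
print.euler <- function(x, ...) {
  cat(sprintf("<euler Z-X'-Y''> x=%.4f y=%.4f z=%.4f (deg)\n", x[1], x[2], x[3]))
  invisible(x)
}

.as_euler <- function(e) {
  if (inherits(e, "euler")) return(e)
  if (is.numeric(e) && length(e) == 3) return(euler_triple(e[1], e[2], e[3]))
  stop("expected an Euler triple (class 'euler' or numeric length 3)")
}

#' Euler decomposition of a quaternion
#'
#' Decomposes under the intrinsic Z-X'-Y'' order, i.e. finds `(x, y, z)` with
#' `R(q) = Rz(z) Rx(x) Ry(y)`. The X angle (the middle, pitch-like rotation)
#' lies in `[-90, 90]`. At gimbal lock (`|sin x| > 1 - 1e-9`, where the Z and
#' Y axes align) the decomposition is not unique; the deterministic tie-break
#' sets `z = 0` and assigns all residual rotation to `y`. `acos`/`asin`
#' arguments are clamped to `[-1, 1]` so no input yields `NaN`.
#'
#' @param q a unit quaternion.
#' @return an `"euler"` triple in degrees.
#' @export
quat_to_euler <- function(q) {
  m <- quat_to_matrix(.as_quat(q))
  sx <- min(1, max(-1, m[3, 2]))
  # atan2 form: |cos x| = ||(R31, R33)||, well-conditioned through the lock
  x <- atan2(sx, sqrt(m[3, 1]^2 + m[3, 3]^2)) / .DEG
  if (abs(sx) > 1 - 1e-9) {
    # z and y are indistinguishable: put everything on y
    z <- 0
    y <- atan2(m[1, 3], m[1, 1]) / .DEG
  } else {
    z <- atan2(-m[1, 2], m[2, 2]) / .DEG
    y <- atan2(-m[3, 1], m[3, 3]) / .DEG
  }
  euler_triple(x, y, z)
}

#' Quaternion from an Euler triple
#'
#' Inverse of [quat_to_euler()]: `q = Qz(z) * Qx(x) * Qy(y)` under the
#' intrinsic Z-X'-Y'' order.
#'
#' @param e an `"euler"` triple (or numeric length 3, degrees).
#' @return a `"quat"`.
#' @export
quat_from_euler <- function(e) {
  e <- .as_euler(e)
  qz <- quat_from_axis_angle(c(0, 0, 1), e[3])
  qx <- quat_from_axis_angle(c(1, 0, 0), e[1])
  qy <- quat_from_axis_angle(c(0, 1, 0), e[2])
  quat_multiply(quat_multiply(qz, qx), qy)
}

#' Relative rotation between parent and child frames
#'
#' The joint rotation carrying the parent frame onto the child frame:
#' `inverse(parent) * child`. Invariant under any common rotation applied to
#' both arguments.
#'
#' @param parent,child unit quaternions (world orientations).
#' @return a `"quat"`.
#' @export
quat_relative <- function(parent, child) {
  quat_multiply(quat_inverse(parent), .as_quat(child))
}

#' Geodesic rotation angle of a quaternion
#'
#' The total rotation angle in degrees, in `[0, 180]`.
#'
#' @param q a unit quaternion.
#' @return angle in degrees.
#' @export
quat_angle <- function(q) {
  q <- .as_quat(q)
  2 * acos(min(1, abs(q[1]))) / .DEG
}
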