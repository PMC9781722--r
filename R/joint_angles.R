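# Three joint-angle measurement methods over parent/child orientation pairs.
#
# Method 1: rotate a reference unit axis by each segment orientation and take
#           the arc-cosine of the dot product -- an unsigned angle in [0, 180].
# Method 2: Euler decomposition of inverse(parent) * child -- the signed
#           relative rotation; the framework's default method.
# Method 3: Euler of the child's stored local rotation, which includes the
#           rig's rest-pose offset; baselines are therefore non-zero whenever
#           the rig does not start at (0, 0, 0).

#' Method 1: unsigned angle between rotated reference axes
#'
#' Rotates `ref_axis` by both segment orientations and returns
#' `acos(dot)` in degrees. The dot product is clamped to `[-1, 1]`, so the
#' result is always finite and in `[0, 180]`; the measure is sign-blind and
#' symmetric in its arguments.
#'
#' @param parent,child unit quaternions (world orientations).
#' @param ref_axis unit 3-vector in the sensor frame (normalized if close).
#' @return angle in degrees, in `[0, 180]`.
#' @export
method1_angle <- function(parent, child, ref_axis) {
  axis <- as.numeric(ref_axis)
  n <- sqrt(sum(axis^2))
  if (!all(is.finite(axis)) || n < 1e-12) stop("ref_axis must be a finite non-zero 3-vector")
  axis <- axis / n
  vp <- quat_rotate(.as_quat(parent), axis)
  vc <- quat_rotate(.as_quat(child), axis)
  d <- min(1, max(-1, sum(vp * vc)))
  acos(d) * 180 / pi
}

#' Method 1 over the three basis axes
#'
#' Convenience wrapper producing the X/Y/Z columns of a validation table:
#' [method1_angle()] with reference axes (1,0,0), (0,1,0), (0,0,1).
#'
#' @inheritParams method1_angle
#' @return named numeric `(x, y, z)` of unsigned angles in degrees.
#' @export
method1_axes <- function(parent, child) {
  c(x = method1_angle(parent, child, c(1, 0, 0)),
    y = method1_angle(parent, child, c(0, 1, 0)),
    z = method1_angle(parent, child, c(0, 0, 1)))
}

#' Method 2: signed Euler angles of the relative rotation
#'
#' `quat_to_euler(inverse(parent) * child)`. Signed, antisymmetric under
#' swapping parent and child, and invariant under any common world rotation.
#'
#' @param parent,child unit quaternions (world orientations).
#' @return an `"euler"` triple in degrees.
#' @export
method2_angles <- function(parent, child) {
  quat_to_euler(quat_relative(parent, child))
}

#' Rest-pose rig for a joint
#'
#' Holds the world rest orientations of the two segments and the child's
#' rest-pose local offset — the local rotation a skeletal hierarchy stores
#' for the child before any joint motion (e.g. an upper arm posed at
#' `(-80, 0, 0)` degrees). Method 3 reads the child's local rotation, so
#' this offset shifts its baseline.
#'
#' @param parent_rest,child_rest unit quaternions (default identity).
#' @param local_offset `"euler"` triple of the child's rest local rotation
#'   (default `(0, 0, 0)`).
#' @return object of class `"segment_rig"`.
#' @export
segment_rig <- function(parent_rest = quat_identity(), child_rest = quat_identity(),
                        local_offset = euler_triple(0, 0, 0)) {
  structure(list(parent_rest = .as_quat(parent_rest),
                 child_rest = .as_quat(child_rest),
                 local_offset = .as_euler(local_offset)),
            class = "segment_rig")
}

#' Method 3: Euler of the child's local rotation including rest pose
#'
#' Composes the rig's rest-pose local offset with the joint motion and
#' decomposes: `quat_to_euler(from_euler(offset) * joint_motion)`. With an
#' identity offset this coincides with Method 2 applied to the same motion.
#'
#' @param rig a `"segment_rig"`.
#' @param joint_motion unit quaternion of the joint rotation away from rest.
#' @return an `"euler"` triple in degrees.
#' @export
method3_angles <- function(rig, joint_motion) {
  stopifnot(inherits(rig, "segment_rig"))
  quat_to_euler(quat_multiply(quat_from_euler(rig$local_offset), .as_quat(joint_motion)))
}

#' Measure a joint from a pair of packets
#'
#' Dispatches to the selected method. The two packets must share a timestamp
#' within `tol` seconds (default half a sample period at `rate` Hz).
#'
#' @param parent_packet,child_packet `"motion_packet"` readings of the two
#'   segments.
#' @param method 1, 2 or 3.
#' @param rig a `"segment_rig"` (required for method 3; for methods 1-2 only
#'   the packets are used).
#' @param joint joint name recorded on the measurement.
#' @param rate nominal stream rate in Hz used for the pairing tolerance.
#' @param tol explicit timestamp tolerance in seconds (overrides `rate`).
#' @return object of class `"joint_measurement"`: fields `joint`, `method`,
#'   `t`, and `angles` (an `"euler"` triple for methods 2-3; named unsigned
#'   per-axis angles for method 1).
#' @export
measure_joint <- function(parent_packet, child_packet, method, rig = segment_rig(),
                          joint = "joint", rate = 60, tol = NULL) {
  stopifnot(inherits(parent_packet, "motion_packet"), inherits(child_packet, "motion_packet"))
  if (!method %in% c(1L, 2L, 3L)) stop("method must be 1, 2 or 3")
  if (is.null(tol)) tol <- 0.5 / rate
  if (abs(parent_packet$t - child_packet$t) > tol)
    stop("packet timestamps differ by more than the pairing tolerance")
  qp <- packet_quat(parent_packet)
  qc <- packet_quat(child_packet)
  angles <- switch(as.integer(method),
    method1_axes(qp, qc),
    method2_angles(qp, qc),
    method3_angles(rig, quat_relative(quat_multiply(qp, quat_from_euler(rig$local_offset)), qc))
  )
  structure(list(joint = joint, method = as.integer(method),
                 t = mean(c(parent_packet$t, child_packet$t)), angles = angles),
            class = "joint_measurement")
}
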