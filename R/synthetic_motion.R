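# Synthetic stand-in for the physical sensors.
#
# Emits fused-orientation packet streams for scripted joint/segment motions
# at a configurable output rate (the device streams 1-60 Hz), with additive
# rotational noise and slow linear drift, so the whole pipeline is testable
# without hardware.
#
# Noise model: an isotropic small rotation composed onto the true
# orientation in the sensor frame. The perturbation is drawn as a rotation
# vector with i.i.d. N(0, sigma^2) components (degrees), so the noise is
# convention-independent and each Euler axis sees Gaussian noise of
# standard deviation sigma.

#' Evaluate with a local RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so the simulator never disturbs global randomness. With
#' `seed = NULL` the expression runs on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.MOTIONS <- c("pivot", "flexion", "extension", "rotation",
              "ulnar", "radial", "pronation", "supination")

#' Motion axis and sign for a joint/motion pair
#'
#' Maps the clinical motion names onto the Euler axis that carries them and
#' the sign of a positive-target rotation, following the sign conventions
#' observed on the monitored segments and joints: trunk segments report
#' pivot on X, flexion on Y and axial rotation on Z (hips swap Y and Z);
#' wrist ulnar/radial deviation is +/-Y, wrist flexion/extension +/-X,
#' pronation/supination +/-Z; knee flexion is -Z; elbow flexion is +Y.
#'
#' @param joint one of `"head"`, `"chest"`, `"hips"`, `"wrist"`, `"knee"`,
#'   `"elbow"`.
#' @param motion one of `"pivot"`, `"flexion"`, `"extension"`, `"rotation"`,
#'   `"ulnar"`, `"radial"`, `"pronation"`, `"supination"`.
#' @return list with `axis` (unit 3-vector), `sign` (+1 or -1) and
#'   `component` (`"x"`, `"y"` or `"z"`).
#' @export
motion_axis <- function(joint, motion) {
  joint <- match.arg(joint, c("head", "chest", "hips", "wrist", "knee", "elbow"))
  motion <- match.arg(motion, .MOTIONS)
  key <- paste(joint, motion, sep = ".")
  map <- list(
    head.pivot = c("x", 1), head.flexion = c("y", 1), head.rotation = c("z", 1),
    chest.pivot = c("x", 1), chest.flexion = c("y", 1), chest.rotation = c("z", 1),
    hips.pivot = c("x", 1), hips.flexion = c("z", 1), hips.rotation = c("y", 1),
    wrist.ulnar = c("y", 1), wrist.radial = c("y", -1),
    wrist.flexion = c("x", 1), wrist.extension = c("x", -1),
    wrist.pronation = c("z", 1), wrist.supination = c("z", -1),
    knee.flexion = c("z", -1), knee.extension = c("z", 1),
    elbow.flexion = c("y", 1), elbow.extension = c("y", -1))
  m <- map[[key]]
  if (is.null(m)) stop("motion '", motion, "' is not defined for joint '", joint, "'")
  comp <- m[1]
  axis <- switch(comp, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  list(axis = axis, sign = as.numeric(m[2]), component = comp)
}

#' Default rest-pose rig for a joint
#'
#' Knee and elbow rigs start at `(0, 0, 0)`; the wrist rig carries a
#' non-trivial rest pose (forearm chain posed away from neutral), which is
#' what shifts Method 3 baselines off zero for the wrist. The wrist offset
#' used here is a synthetic stand-in with the documented upper-arm rest
#' angle; the original hand rest pose is not published.
#'
#' @param joint joint name as in [motion_axis()].
#' @return a `"segment_rig"`.
#' @export
default_rig <- function(joint) {
  if (identical(joint, "wrist")) {
    segment_rig(parent_rest = quat_from_euler(euler_triple(0, 0, 90)),
                local_offset = euler_triple(-80, 0, 0))
  } else {
    segment_rig()
  }
}

#' Motion profile for the simulator
#'
#' @param segment segment/joint name (also used as the sensor id prefix).
#' @param motion motion type, see [motion_axis()].
#' @param target target angle in degrees.
#' @param ramp_time,hold_time seconds spent ramping 0 -> target and holding
#'   it. Defaults: 1 s ramp, 2 s hold (a deliberate, held exercise pose).
#' @param rate output rate in Hz, within the device's 1-60 Hz streaming
#'   range (default 60, the top rate).
#' @param sigma rotational noise, degrees (s.d. of each rotation-vector
#'   component). Default 0.
#' @param drift slow bias drift in degrees per minute about the motion axis.
#'   Default 0.
#' @param seed integer seed for reproducibility (`NULL` = current stream).
#' @return object of class `"motion_profile"`.
#' @export
motion_profile <- function(segment = "head", motion = "pivot", target = 30,
                           ramp_time = 1, hold_time = 2, rate = 60,
                           sigma = 0, drift = 0, seed = NULL) {
  if (!is.numeric(rate) || rate < 1 || rate > 60)
    stop("rate must be within the streaming range [1, 60] Hz")
  if (sigma < 0 || drift < 0) stop("sigma and drift must be non-negative")
  if (ramp_time < 0 || hold_time < 0) stop("ramp_time and hold_time must be non-negative")
  structure(list(segment = segment, motion = motion, target = as.numeric(target),
                 ramp_time = ramp_time, hold_time = hold_time, rate = rate,
                 sigma = sigma, drift = drift, seed = seed),
            class = "motion_profile")
}

# rotation-vector (degrees) -> quaternion
.rotvec_quat <- function(v) {
  ang <- sqrt(sum(v^2))
  if (ang < 1e-12) return(quat_identity())
  quat_from_axis_angle(v / ang, ang)
}

# n i.i.d. noise quaternions, sigma in degrees (list; identity when sigma = 0)
.noise_quats <- function(n, sigma) {
  if (sigma == 0) return(rep(list(quat_identity()), n))
  eps <- matrix(stats::rnorm(3 * n, sd = sigma), ncol = 3)
  lapply(seq_len(n), function(i) .rotvec_quat(eps[i, ]))
}

#' Script a single-segment motion as a packet stream
#'
#' Ramps linearly from 0 to the target angle over `ramp_time`, then holds it
#' for `hold_time`, sampling at `rate` Hz from t = 0. The noiseless hold
#' phase equals the target rotation about the motion's axis exactly; noise
#' is an isotropic rotation perturbation (see module header) and drift a
#' linear angle ramp on the motion axis. Deterministic given the seed.
#'
#' @param profile a `"motion_profile"`.
#' @param joint joint name used to resolve the motion axis (default: the
#'   profile's segment if it names a joint, else `"head"`).
#' @return list of `"motion_packet"` objects.
#' @export
script_motion <- function(profile, joint = NULL) {
  stopifnot(inherits(profile, "motion_profile"))
  if (is.null(joint)) {
    joint <- if (profile$segment %in% c("head", "chest", "hips", "wrist", "knee", "elbow"))
      profile$segment else "head"
  }
  ax <- motion_axis(joint, profile$motion)
  n_ramp <- round(profile$ramp_time * profile$rate)
  n_hold <- round(profile$hold_time * profile$rate)
  n <- n_ramp + n_hold
  if (n == 0) return(list())
  t <- (seq_len(n) - 1) / profile$rate
  frac <- c(if (n_ramp > 0) seq_len(n_ramp) / n_ramp, rep(1, n_hold))
  angle <- ax$sign * profile$target * frac + ax$sign * profile$drift * t / 60
  with_seed(profile$seed, {
    noise <- .noise_quats(n, profile$sigma)
    lapply(seq_len(n), function(i) {
      q <- quat_from_axis_angle(ax$axis, angle[i])
      if (profile$sigma > 0) q <- quat_multiply(q, noise[[i]])
      motion_packet(profile$segment, t[i], q)
    })
  })
}

#' Simulate a goniometer validation sweep
#'
#' Reproduces the bench protocol used to validate the sensors against a
#' goniometer: the joint is posed at each target angle of `grid` in turn
#' and held steady while both segment sensors stream. The parent sensor
#' holds its rest orientation; the child is rotated by the (signed) target
#' about the motion's axis. Both sensors receive independent rotational
#' noise. Timestamps run continuously across poses.
#'
#' @param joint,motion joint and motion type, see [motion_axis()].
#' @param grid goniometer target angles in degrees (default
#'   `c(0, 10, 20, 30, 40, 50)`), each within `[-180, 180)`.
#' @param rate output rate in Hz (default 60).
#' @param hold_time seconds each pose is held (default 2).
#' @param sigma rotational noise in degrees (default 0).
#' @param drift drift in degrees/minute on the child's motion axis
#'   (default 0).
#' @param seed integer seed (`NULL` = current stream).
#' @param rig a `"segment_rig"`; default [default_rig()] for the joint.
#'   Carried as metadata for Method 3.
#' @return data.frame with one row per tick: `target`, `t`, parent
#'   quaternion `pw, px, py, pz`, child quaternion `cw, cx, cy, cz`;
#'   attributes `joint`, `motion`, `axis` (from [motion_axis()]), `sigma`,
#'   `rate`, `rig`.
#' @export
simulate_goniometer_sweep <- function(joint, motion, grid = c(0, 10, 20, 30, 40, 50),
                                      rate = 60, hold_time = 2, sigma = 0, drift = 0,
                                      seed = NULL, rig = default_rig(joint)) {
  if (any(grid < -180 | grid >= 180)) stop("grid angles must lie in [-180, 180)")
  ax <- motion_axis(joint, motion)
  n_hold <- max(1L, round(hold_time * rate))
  n <- n_hold * length(grid)
  target <- rep(grid, each = n_hold)
  t <- (seq_len(n) - 1) / rate
  parent_rest <- rig$parent_rest
  with_seed(seed, {
    np <- .noise_quats(n, sigma)
    nc <- .noise_quats(n, sigma)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      qp <- parent_rest
      ang <- ax$sign * target[i] + ax$sign * drift * t[i] / 60
      qc <- quat_multiply(parent_rest, quat_from_axis_angle(ax$axis, ang))
      if (sigma > 0) {
        qp <- quat_multiply(qp, np[[i]])
        qc <- quat_multiply(qc, nc[[i]])
      }
      rows[[i]] <- c(target[i], t[i], unclass(qp), unclass(qc))
    }
    m <- do.call(rbind, rows)
    df <- data.frame(m)
    names(df) <- c("target", "t", "pw", "px", "py", "pz", "cw", "cx", "cy", "cz")
    attr(df, "joint") <- joint
    attr(df, "motion") <- motion
    attr(df, "axis") <- ax
    attr(df, "sigma") <- sigma
    attr(df, "rate") <- rate
    attr(df, "rig") <- rig
    df
  })
}

#' Packets of one sweep row
#'
#' @param sweep data.frame from [simulate_goniometer_sweep()].
#' @param i row index.
#' @return list with `parent` and `child` `"motion_packet"`s.
#' @export
sweep_packets <- function(sweep, i) {
  r <- sweep[i, ]
  list(parent = motion_packet("parent", r$t, quat(r$pw, r$px, r$py, r$pz, canonical = FALSE)),
       child = motion_packet("child", r$t, quat(r$cw, r$cx, r$cy, r$cz, canonical = FALSE)))
}
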