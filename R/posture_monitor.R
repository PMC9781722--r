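# 13-segment body model, scenario range-of-motion limits, violation events.
#
# The body model mirrors the monitoring loop's array of 13 per-segment
# structs: orientation quaternion, Euler triples for rotation, correction
# (the calibrated angles) and positional control, the sensor number, and the
# segment name. Safe-range checking follows the occupational guidance that
# sustained postures beyond ~20 degrees from neutral carry musculoskeletal
# risk, relaxed to a +/-30 degree spinal range; a violation event is a
# flagged excursion sustained for at least the configured duration.

.SEGMENTS <- c("head", "chest", "pelvis",
               "upper_arm_l", "upper_arm_r", "lower_arm_l", "lower_arm_r",
               "hand_l", "hand_r",
               "upper_leg_l", "upper_leg_r", "lower_leg_l", "lower_leg_r")

#' The 13 tracked body segments
#' @return character vector of the fixed segment names.
#' @export
body_segments <- function() .SEGMENTS

#' Construct the 13-segment body model
#'
#' One state per segment: `name`, `sensor_id`, `q` (orientation),
#' `rotation` (raw Euler), `correction` (calibrated Euler), `position`
#' (positional-control triple, unused by the monitor but kept to mirror the
#' per-segment struct), `t` (time of last update).
#'
#' @param sensor_map named character vector mapping segment name ->
#'   sensor id; defaults to sensors `"s1"`..`"s13"` in [body_segments()]
#'   order.
#' @return object of class `"body_model"`: named list of segment states.
#' @export
body_model <- function(sensor_map = NULL) {
  if (is.null(sensor_map)) {
    sensor_map <- stats::setNames(paste0("s", seq_along(.SEGMENTS)), .SEGMENTS)
  }
  miss <- setdiff(.SEGMENTS, names(sensor_map))
  if (length(miss)) stop("sensor_map is missing segment(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(names(sensor_map))) stop("segment names must be unique")
  model <- lapply(.SEGMENTS, function(nm) {
    list(name = nm, sensor_id = unname(sensor_map[[nm]]), q = quat_identity(),
         rotation = euler_triple(0, 0, 0), correction = euler_triple(0, 0, 0),
         position = euler_triple(0, 0, 0), t = NA_real_)
  })
  names(model) <- .SEGMENTS
  structure(model, class = "body_model")
}

#' Update the body model from a packet batch
#'
#' Applies each packet to the segment owning its sensor id: orientation,
#' raw Euler rotation and calibrated correction angles are refreshed.
#' Packets are applied in timestamp order, so when one sensor appears more
#' than once the later timestamp wins. Packets from unknown sensors are
#' skipped with a message.
#'
#' @param model a `"body_model"`.
#' @param packets list of `"motion_packet"` objects (possibly empty).
#' @param calibration a `"calibration_state"` or `NULL`.
#' @return the updated `"body_model"`.
#' @export
update_body <- function(model, packets, calibration = NULL) {
  stopifnot(inherits(model, "body_model"))
  if (length(packets) == 0) return(model)
  ord <- order(vapply(packets, function(p) p$t, numeric(1)))
  by_sensor <- stats::setNames(names(model), vapply(model, function(s) s$sensor_id, character(1)))
  for (p in packets[ord]) {
    seg <- unname(by_sensor[p$sensor_id])
    if (is.na(seg)) {
      message("skipping packet from unknown sensor '", p$sensor_id, "'")
      next
    }
    q <- packet_quat(p)
    rot <- quat_to_euler(q)
    cal <- if (is.null(calibration)) rot else
      suppressWarnings(apply_calibration(calibration, rot, segment = seg))
    model[[seg]]$q <- q
    model[[seg]]$rotation <- rot
    model[[seg]]$correction <- cal
    model[[seg]]$t <- p$t
  }
  model
}

#' Scenario-specific posture limits
#'
#' Bundles per-segment, per-axis safe ranges with the minimum sustained
#' duration that turns an excursion into a violation event.
#'
#' @param scenario integer scenario id in 0..4.
#' @param segments named list: per monitored segment, a named numeric
#'   `c(x=, y=, z=)` of positive limit magnitudes in degrees.
#' @param min_duration minimum sustained duration in seconds (default 5;
#'   the guidance quantifies neither "sustained" nor "long period", so this
#'   is a configurable default).
#' @return object of class `"posture_limits"`.
#' @export
posture_limits <- function(scenario = 0L, segments = list(), min_duration = 5) {
  if (length(segments)) {
    ok <- vapply(segments, function(l) all(c("x", "y", "z") %in% names(l)) && all(l > 0), logical(1))
    if (!all(ok)) stop("each segment limit must be positive and name axes x, y, z")
  }
  if (min_duration < 0) stop("min_duration must be non-negative")
  structure(list(scenario = as.integer(scenario), segments = segments,
                 min_duration = as.numeric(min_duration)),
            class = "posture_limits")
}

#' Preset limits for a monitoring scenario
#'
#' Scenario ids follow the dropdown of the original monitor: 0 = none
#' (no limits), 1 = standing, 2 = sitting, 3 = joint movement, 4 = lifting.
#' Scenarios 1-4 monitor the head, chest and pelvis with a +/-30 degree
#' safe range on every axis. Per the segment sign conventions, pivot loads
#' the X axis for all three; flexion and axial rotation load Y and Z for
#' head and chest but Z and Y for the pelvis — with symmetric limits the
#' swap changes labels, not thresholds.
#'
#' @param scenario integer id in 0..4.
#' @param limit safe-range magnitude in degrees (default 30).
#' @param min_duration minimum sustained duration in seconds (default 5).
#' @return a `"posture_limits"`.
#' @export
scenario_config <- function(scenario, limit = 30, min_duration = 5) {
  if (length(scenario) != 1 || is.na(scenario) || scenario %% 1 != 0 ||
      scenario < 0 || scenario > 4)
    stop("scenario id must be an integer between 0 and 4")
  scenario <- as.integer(scenario)
  if (scenario == 0L) return(posture_limits(0L, list(), min_duration))
  axes <- c(x = limit, y = limit, z = limit)
  posture_limits(scenario,
                 list(head = axes, chest = axes, pelvis = axes),
                 min_duration)
}

#' Check one segment against its limits
#'
#' Strict comparison: an axis is flagged iff `|angle| > limit` on that axis
#' (an angle exactly at the limit is not flagged). Uses the segment's
#' calibrated `correction` angles.
#'
#' @param segment one segment state from a `"body_model"`.
#' @param limits a `"posture_limits"`.
#' @return named logical `c(x=, y=, z=)`; all `FALSE` when the segment is
#'   not monitored in this scenario.
#' @export
check_limits <- function(segment, limits) {
  stopifnot(inherits(limits, "posture_limits"))
  lim <- limits$segments[[segment$name]]
  flags <- c(x = FALSE, y = FALSE, z = FALSE)
  if (is.null(lim)) return(flags)
  ang <- as.numeric(segment$correction)
  for (k in 1:3) flags[k] <- abs(ang[k]) > lim[c("x", "y", "z")[k]]
  flags
}

#' Detect sustained range-of-motion violations in an angle trace
#'
#' `trace` holds per-sample calibrated angles for segment/axis series
#' (columns `t`, `segment`, `axis`, `angle`). Within each series, samples
#' with `|angle|` strictly above the limit form runs; consecutive flagged
#' samples are chained when their spacing is under two sample periods (so a
#' dropped sample is bridged but an in-range sample breaks the run). Runs
#' sustained for at least `min_duration` seconds become one event each.
#'
#' @param trace data.frame with columns `t` (seconds, non-decreasing per
#'   series), `segment`, `axis` (`"x"/"y"/"z"`), `angle` (degrees).
#' @param limits a `"posture_limits"`.
#' @param rate nominal sample rate in Hz (default 60), used for the
#'   bridging window.
#' @return data.frame of events: `segment`, `axis`, `start`, `end`, `peak`
#'   (signed angle of largest magnitude), zero rows when nothing sustained.
#' @export
sustained_violation <- function(trace, limits, rate = 60) {
  stopifnot(inherits(limits, "posture_limits"))
  need <- c("t", "segment", "axis", "angle")
  miss <- setdiff(need, names(trace))
  if (length(miss)) stop("trace is missing column(s): ", paste(miss, collapse = ", "))
  empty <- data.frame(segment = character(0), axis = character(0),
                      start = numeric(0), end = numeric(0), peak = numeric(0))
  if (nrow(trace) == 0 || length(limits$segments) == 0) return(empty)
  period <- 1 / rate
  out <- list()
  for (key in unique(paste(trace$segment, trace$axis))) {
    parts <- strsplit(key, " ", fixed = TRUE)[[1]]
    seg <- parts[1]; axis <- parts[2]
    lim <- limits$segments[[seg]][axis]
    if (is.null(lim) || is.na(lim)) next
    s <- trace[trace$segment == seg & trace$axis == axis, ]
    if (is.unsorted(s$t)) stop("trace timestamps must be non-decreasing within a series")
    flagged <- which(abs(s$angle) > lim)
    if (!length(flagged)) next
    # split flagged indices into runs: chain while spacing < 2 sample periods
    brk <- which(diff(s$t[flagged]) >= 2 * period - 1e-12)
    run_id <- cumsum(c(1, seq_along(flagged)[-1] %in% (brk + 1)))
    for (r in split(flagged, run_id)) {
      dur <- s$t[r[length(r)]] - s$t[r[1]]
      if (dur >= limits$min_duration) {
        pk <- s$angle[r][which.max(abs(s$angle[r]))]
        out[[length(out) + 1]] <- data.frame(segment = seg, axis = axis,
                                             start = s$t[r[1]], end = s$t[r[length(r)]],
                                             peak = pk)
      }
    }
  }
  if (!length(out)) return(empty)
  ev <- do.call(rbind, out)
  ev[order(ev$start, ev$segment, ev$axis), , drop = FALSE]
}

#' Run the monitor over a packet stream
#'
#' Feeds packets through the body model, applying calibration and
#' (re-)capturing it at each time in `calibrate_at` (the "C button"
#' trigger), builds the calibrated angle trace for the monitored segments,
#' and extracts sustained violation events.
#'
#' @param packets list of `"motion_packet"` objects.
#' @param limits a `"posture_limits"` (e.g. from [scenario_config()]).
#' @param model a `"body_model"`; default mapping `s1..s13`.
#' @param calibration initial `"calibration_state"` or `NULL`.
#' @param calibrate_at numeric times (seconds); at the first packet at or
#'   after each, the current rotations of all monitored segments are
#'   captured as the new reference.
#' @param rate nominal rate in Hz for event bridging (default 60).
#' @return list with `events` (data.frame as [sustained_violation()]),
#'   `trace` (the angle trace), `model` and `calibration` (final states).
#' @export
monitor_stream <- function(packets, limits, model = body_model(), calibration = NULL,
                           calibrate_at = numeric(0), rate = 60) {
  stopifnot(inherits(limits, "posture_limits"))
  monitored <- names(limits$segments)
  ord <- order(vapply(packets, function(p) p$t, numeric(1)))
  packets <- packets[ord]
  calibrate_at <- sort(calibrate_at)
  rows <- list()
  for (p in packets) {
    while (length(calibrate_at) && p$t >= calibrate_at[1]) {
      readings <- lapply(model[if (length(monitored)) monitored else names(model)],
                         function(s) s$rotation)
      calibration <- capture_reference(readings, timestamp = calibrate_at[1])
      calibrate_at <- calibrate_at[-1]
    }
    model <- update_body(model, list(p), calibration)
    seg <- NULL
    for (nm in names(model)) if (identical(model[[nm]]$sensor_id, p$sensor_id)) { seg <- nm; break }
    if (is.null(seg) || !(seg %in% monitored)) next
    ang <- model[[seg]]$correction
    rows[[length(rows) + 1]] <- data.frame(
      t = p$t, segment = seg, axis = c("x", "y", "z"), angle = as.numeric(ang))
  }
  trace <- if (length(rows)) do.call(rbind, rows) else
    data.frame(t = numeric(0), segment = character(0), axis = character(0), angle = numeric(0))
  events <- sustained_violation(trace, limits, rate = rate)
  list(events = events, trace = trace, model = model, calibration = calibration)
}
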