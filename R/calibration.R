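# Reference-pose calibration (re-zeroing).
#
# IMUs drift slowly; the monitor re-zeroes by capturing the current Euler
# reading of every active segment and subtracting it, per axis, from all
# subsequent readings, wrapping the difference into [-180, 180). The
# subtraction is deliberately per-axis in Euler space (not a quaternion
# composition): that is the re-zeroing rule the monitoring loop applies,
# exact for single-axis motion, approximate otherwise.

#' Wrap an angle into [-180, 180)
#'
#' Result is congruent to the input modulo 360 and lies in the half-open
#' interval `[-180, 180)` (so `wrap_angle(180)` is `-180`).
#'
#' @param a angle(s) in degrees; must be finite.
#' @return wrapped angle(s), same length as `a`.
#' @examples
#' wrap_angle(190)   # -170
#' wrap_angle(-185)  #  175
#' @export
wrap_angle <- function(a) {
  a <- as.numeric(a)
  if (!all(is.finite(a))) stop("angle must be finite")
  ((a + 180) %% 360) - 180
}

#' Capture a calibration reference
#'
#' Takes the current per-segment Euler readings and stores them (wrapped)
#' as the reference to subtract from later readings. All active segments
#' are captured atomically.
#'
#' @param readings named list of Euler triples (class `"euler"` or numeric
#'   length 3, degrees), one per active segment.
#' @param timestamp capture time in seconds (default 0).
#' @return object of class `"calibration_state"` with fields `reference`
#'   (named list of wrapped triples) and `timestamp`.
#' @export
capture_reference <- function(readings, timestamp = 0) {
  if (!is.list(readings) || is.null(names(readings)) || any(!nzchar(names(readings))))
    stop("readings must be a named list of Euler triples")
  bad <- vapply(readings, function(r) is.null(r) || any(!is.finite(as.numeric(r))), logical(1))
  if (any(bad)) stop("missing or non-finite reading for segment(s): ",
                     paste(names(readings)[bad], collapse = ", "))
  ref <- lapply(readings, function(r) { e <- .as_euler(r); e })
  structure(list(reference = ref, timestamp = as.numeric(timestamp)),
            class = "calibration_state")
}

#' Apply a calibration reference to a reading
#'
#' Per-axis difference `reading - reference`, wrapped into `[-180, 180)`.
#' If the segment was never captured the reading passes through unchanged
#' with a warning.
#'
#' @param state a `"calibration_state"` from [capture_reference()], or
#'   `NULL` for no calibration.
#' @param reading an Euler triple (degrees).
#' @param segment segment name to look up in the state; when `state` holds
#'   exactly one segment it defaults to that one.
#' @return calibrated `"euler"` triple.
#' @export
apply_calibration <- function(state, reading, segment = NULL) {
  reading <- .as_euler(reading)
  if (is.null(state)) return(reading)
  stopifnot(inherits(state, "calibration_state"))
  if (is.null(segment)) {
    if (length(state$reference) == 1L) segment <- names(state$reference)
    else stop("segment must be named when the state holds several segments")
  }
  ref <- state$reference[[segment]]
  if (is.null(ref)) {
    warning("segment '", segment, "' has no calibration reference; passing through")
    return(reading)
  }
  euler_triple(reading[1] - ref[1], reading[2] - ref[2], reading[3] - ref[3])
}

#' Persist / restore calibration state as JSON
#'
#' @param state a `"calibration_state"`.
#' @param path file path for the JSON document.
#' @return `save_calibration` returns `path` invisibly; `load_calibration`
#'   returns the restored `"calibration_state"`.
#' @export
save_calibration <- function(state, path) {
  stopifnot(inherits(state, "calibration_state"))
  doc <- list(timestamp = state$timestamp,
              reference = lapply(state$reference, function(e) as.numeric(e)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  capture_reference(lapply(doc$reference, function(v) euler_triple(v[1], v[2], v[3])),
                    timestamp = doc$timestamp)
}
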