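# Packet dialect and CSV logging.
#
# One JSON object per line carries one fused orientation sample:
#   {"id":"s1","t":0.0,"wq":1,"xq":0,"yq":0,"zq":0}
# "wq" is the real (scalar) component, xq/yq/zq the imaginary components.
# CSV logs use columns timestamp, sensor_id, wq, xq, yq, zq; parsing is
# header-driven so column order is free.

#' A single orientation packet
#'
#' @param sensor_id sensor identifier (character scalar).
#' @param timestamp seconds from stream start.
#' @param q orientation as a `"quat"` (or numeric length 4, scalar first).
#' @return object of class `"motion_packet"` with fields `sensor_id`, `t`,
#'   `wq`, `xq`, `yq`, `zq`.
#' @export
motion_packet <- function(sensor_id, timestamp, q) {
  q <- .as_quat(q)
  if (!is.finite(timestamp)) stop("timestamp must be finite")
  structure(list(sensor_id = as.character(sensor_id), t = as.numeric(timestamp),
                 wq = unname(q[1]), xq = unname(q[2]), yq = unname(q[3]), zq = unname(q[4])),
            class = "motion_packet")
}

#' Quaternion carried by a packet
#' @param p a `"motion_packet"`.
#' @return a `"quat"`.
#' @export
packet_quat <- function(p) quat(p$wq, p$xq, p$yq, p$zq, canonical = FALSE)

#' Parse one packet line
#'
#' Accepts one JSON object per line with keys `id`, `t`, `wq`, `xq`, `yq`,
#' `zq`; unknown keys are ignored. The quaternion must be unit within 1e-3
#' on ingest and is renormalized. A missing field is an error naming it.
#'
#' @param line character scalar holding one JSON object.
#' @return a `"motion_packet"`.
#' @export
parse_packet <- function(line) {
  obj <- tryCatch(jsonlite::fromJSON(line, simplifyVector = TRUE),
                  error = function(e) stop("malformed packet JSON: ", conditionMessage(e)))
  need <- c("id", "t", "wq", "xq", "yq", "zq")
  miss <- setdiff(need, names(obj))
  if (length(miss)) stop("packet is missing field(s): ", paste(miss, collapse = ", "))
  comp <- as.numeric(c(obj$wq, obj$xq, obj$yq, obj$zq))
  if (any(!is.finite(comp))) stop("packet has non-finite quaternion component")
  n <- sqrt(sum(comp^2))
  if (abs(n - 1) > 1e-3) stop("packet quaternion is not unit within 1e-3 (norm ", signif(n, 6), ")")
  motion_packet(obj$id, as.numeric(obj$t), quat(comp[1], comp[2], comp[3], comp[4], canonical = FALSE))
}

#' Serialize a packet to one JSON line
#'
#' @param p a `"motion_packet"` (all components finite).
#' @return character scalar (no trailing newline) parseable by
#'   [parse_packet()].
#' @export
serialize_packet <- function(p) {
  stopifnot(inherits(p, "motion_packet"))
  comp <- c(p$wq, p$xq, p$yq, p$zq, p$t)
  if (any(!is.finite(comp))) stop("cannot serialize non-finite packet component")
  # %.17g keeps doubles bit-exact through a parse/serialize cycle
  num <- function(v) sprintf("%.17g", v)
  id <- gsub('"', '\\\\"', p$sensor_id)
  sprintf('{"id":"%s","t":%s,"wq":%s,"xq":%s,"yq":%s,"zq":%s}',
          id, num(p$t), num(p$wq), num(p$xq), num(p$yq), num(p$zq))
}

#' Read / write a newline-delimited JSON packet stream
#'
#' @param path file path (or connection for reading).
#' @param packets list of `"motion_packet"` objects.
#' @return `read_packet_stream` returns a list of packets;
#'   `write_packet_stream` returns `path` invisibly.
#' @export
read_packet_stream <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, parse_packet)
}

#' @rdname read_packet_stream
#' @export
write_packet_stream <- function(packets, path) {
  writeLines(vapply(packets, serialize_packet, character(1)), con = path)
  invisible(path)
}

.CSV_COLS <- c("timestamp", "sensor_id", "wq", "xq", "yq", "zq")

#' Read / write a CSV orientation log
#'
#' Columns `timestamp, sensor_id, wq, xq, yq, zq` in any order (the header
#' decides). Round trips are lossless: numbers are written with 17
#' significant digits. Order of rows is preserved.
#'
#' @param path CSV file path.
#' @param packets list of `"motion_packet"` objects.
#' @return `read_csv_log` returns a list of packets in file order;
#'   `write_csv_log` returns `path` invisibly.
#' @export
read_csv_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.CSV_COLS, names(df))
  if (length(miss)) stop("CSV log is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) return(list())
  lapply(seq_len(nrow(df)), function(i)
    motion_packet(df$sensor_id[i], df$timestamp[i],
                  quat(df$wq[i], df$xq[i], df$yq[i], df$zq[i], canonical = FALSE)))
}

#' @rdname read_csv_log
#' @export
write_csv_log <- function(packets, path) {
  num <- function(field) vapply(packets, function(p) p[[field]], numeric(1))
  fmt <- function(v) sprintf("%.17g", v)
  df <- data.frame(
    timestamp = if (length(packets)) fmt(num("t")) else character(0),
    sensor_id = vapply(packets, function(p) p$sensor_id, character(1)),
    wq = if (length(packets)) fmt(num("wq")) else character(0),
    xq = if (length(packets)) fmt(num("xq")) else character(0),
    yq = if (length(packets)) fmt(num("yq")) else character(0),
    zq = if (length(packets)) fmt(num("zq")) else character(0),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
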