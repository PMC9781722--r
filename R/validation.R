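# Goniometer-sweep validation tables and accuracy summaries.
#
# A validation table has one row per goniometer target angle and one column
# per (method, axis) cell, the shape of the published bench-comparison
# grids. Cells from a simulated sweep are the method output at that steady
# pose, averaged (circular mean) over the hold samples — the analogue of
# reading a held pose off the display.
#
# The headline "percent accuracy" of the original study is not defined
# there, so accuracy summaries report MAE, maximum absolute error, the
# within +/-1 degree proportion, and a clearly-labelled range-normalized
# percent (100 * (1 - MAE / full scale)).

.circ_mean <- function(deg) {
  r <- deg * pi / 180
  wrap_angle(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

#' Construct a validation table
#'
#' @param df data.frame whose first column is `target` (strictly
#'   increasing goniometer angles) followed by one numeric column per cell
#'   series (e.g. `m1_x`, `m2_z`, `head_x`); `NA` marks missing cells.
#' @param joint,motion,sigma metadata recorded as attributes.
#' @return `df` with class `"validation_table"`.
#' @export
validation_table <- function(df, joint = NA_character_, motion = NA_character_,
                             sigma = NA_real_) {
  if (!is.data.frame(df) || names(df)[1] != "target")
    stop("first column must be 'target'")
  if (nrow(df) && any(diff(df$target) <= 0))
    stop("target angles must be strictly increasing")
  attr(df, "joint") <- joint
  attr(df, "motion") <- motion
  attr(df, "sigma") <- sigma
  class(df) <- c("validation_table", "data.frame")
  df
}

#' Build a validation table from a simulated sweep
#'
#' For every target angle of the sweep and every requested method, computes
#' the method output at each held sample and stores the circular mean over
#' the hold as the cell value. Method 1 fills unsigned per-reference-axis
#' columns `m1_x/m1_y/m1_z`; Methods 2 and 3 fill signed Euler columns.
#'
#' @param sweep data.frame from [simulate_goniometer_sweep()] (non-empty).
#' @param methods subset of `c(1, 2, 3)` (default all three).
#' @param rig a `"segment_rig"` for Method 3; defaults to the sweep's.
#' @return a `"validation_table"`.
#' @export
build_validation_table <- function(sweep, methods = c(1, 2, 3), rig = NULL) {
  if (is.null(sweep) || nrow(sweep) == 0) stop("sweep dataset is empty")
  if (!all(methods %in% 1:3)) stop("methods must be a subset of {1, 2, 3}")
  if (is.null(rig)) rig <- attr(sweep, "rig")
  if (is.null(rig)) rig <- segment_rig()
  offset_q <- quat_from_euler(rig$local_offset)
  targets <- unique(sweep$target)
  cols <- unlist(lapply(sort(methods), function(m) paste0("m", m, "_", c("x", "y", "z"))))
  out <- matrix(NA_real_, nrow = length(targets), ncol = length(cols),
                dimnames = list(NULL, cols))
  for (ti in seq_along(targets)) {
    s <- sweep[sweep$target == targets[ti], ]
    n <- nrow(s)
    vals <- lapply(cols, function(cc) numeric(n))
    names(vals) <- cols
    for (i in seq_len(n)) {
      qp <- quat(s$pw[i], s$px[i], s$py[i], s$pz[i], canonical = FALSE)
      qc <- quat(s$cw[i], s$cx[i], s$cy[i], s$cz[i], canonical = FALSE)
      rel <- quat_relative(qp, qc)
      if (1 %in% methods) {
        a <- method1_axes(qp, qc)
        vals$m1_x[i] <- a[1]; vals$m1_y[i] <- a[2]; vals$m1_z[i] <- a[3]
      }
      if (2 %in% methods) {
        e <- quat_to_euler(rel)
        vals$m2_x[i] <- e[1]; vals$m2_y[i] <- e[2]; vals$m2_z[i] <- e[3]
      }
      if (3 %in% methods) {
        e <- quat_to_euler(quat_multiply(offset_q, rel))
        vals$m3_x[i] <- e[1]; vals$m3_y[i] <- e[2]; vals$m3_z[i] <- e[3]
      }
    }
    for (cc in cols) out[ti, cc] <- .circ_mean(vals[[cc]])
  }
  df <- data.frame(target = targets, out, check.names = FALSE)
  validation_table(df, joint = attr(sweep, "joint"), motion = attr(sweep, "motion"),
                   sigma = attr(sweep, "sigma"))
}

#' Accuracy summaries over validation-table cells
#'
#' Errors are `|sign * cell - target|` over the selected columns, skipping
#' missing (`NA`) cells. `percent_accuracy` is the range-normalized
#' `100 * (1 - MAE / full_scale)` with the sweep's 50 degree full scale by
#' default; it is reported as one of several labelled summaries, not as a
#' reconstruction of any previously published percent figure.
#'
#' @param table a `"validation_table"` (or plain data.frame with a
#'   `target` first column).
#' @param columns character vector of cell columns to summarize (e.g.
#'   `"m2_y"`); default: every non-target column.
#' @param signs numeric sign per column (+1/-1, recycled) applied before
#'   comparing with the target, for motions whose active axis runs negative.
#' @param full_scale full scale in degrees for the percent figure
#'   (default 50).
#' @return list with `mae`, `max_abs_error`, `within_1deg` (proportion) and
#'   `percent_accuracy`, plus `n_cells`.
#' @export
accuracy_metrics <- function(table, columns = NULL, signs = 1, full_scale = 50) {
  if (is.null(columns)) columns <- setdiff(names(table), "target")
  miss <- setdiff(columns, names(table))
  if (length(miss)) stop("unknown column(s): ", paste(miss, collapse = ", "))
  signs <- rep_len(signs, length(columns))
  errs <- numeric(0)
  for (j in seq_along(columns)) {
    v <- table[[columns[j]]]
    ok <- !is.na(v)
    errs <- c(errs, abs(signs[j] * v[ok] - table$target[ok]))
  }
  if (!length(errs)) stop("no non-missing cells in the selected columns")
  mae <- mean(errs)
  list(mae = mae,
       max_abs_error = max(errs),
       within_1deg = mean(errs <= 1),
       percent_accuracy = 100 * (1 - mae / full_scale),
       n_cells = length(errs))
}

#' Load an embedded copy of a published validation grid
#'
#' The package ships plain-text copies of the nine goniometer-comparison
#' grids (full-body movement plus eight joint motions) under
#' `inst/extdata/`. `NAN` and `N/A` cells are loaded as `NA`.
#'
#' @param n table number, 2..10: 2 = full-body (head/chest/hips); 3/4 =
#'   wrist ulnar/radial deviation; 5/6 = wrist flexion/extension; 7/8 =
#'   wrist pronation/supination; 9 = knee flexion; 10 = elbow flexion.
#' @return a `"validation_table"`.
#' @export
load_printed_table <- function(n) {
  if (!n %in% 2:10) stop("table number must be between 2 and 10")
  path <- system.file("extdata", sprintf("printed_table_%02d.tsv", n),
                      package = "imuposture", mustWork = TRUE)
  df <- utils::read.delim(path, check.names = FALSE,
                          na.strings = c("NAN", "N/A", "NA"))
  df[] <- lapply(df, as.numeric)
  meta <- list(`2` = c("full_body", "mixed"),
               `3` = c("wrist", "ulnar"), `4` = c("wrist", "radial"),
               `5` = c("wrist", "flexion"), `6` = c("wrist", "extension"),
               `7` = c("wrist", "pronation"), `8` = c("wrist", "supination"),
               `9` = c("knee", "flexion"), `10` = c("elbow", "flexion"))[[as.character(n)]]
  validation_table(df, joint = meta[1], motion = meta[2])
}

#' Write a validation table as CSV
#'
#' @param table a `"validation_table"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_validation_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
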