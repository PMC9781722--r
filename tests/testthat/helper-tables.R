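# Verbatim transcription of the published goniometer-comparison grids,
# kept separate from the copies shipped in inst/extdata so the two can be
# checked against each other cell-for-cell. NA marks NAN / N/A cells.

ref_joint_cols <- c("m1_x", "m1_y", "m1_z", "m2_x", "m2_y", "m2_z", "m3_x", "m3_y", "m3_z")

ref_grid <- c(0, 10, 20, 30, 40, 50)

.ref_tab <- function(cells, cols = ref_joint_cols) {
  m <- matrix(cells, nrow = 6, byrow = TRUE)
  df <- data.frame(target = ref_grid, m)
  names(df) <- c("target", cols)
  df
}

ref_tables <- list(
  `2` = .ref_tab(c(
     0,  0,  0,  0,  0,  0,  0,  0,  0,
    10, 10,  8, 11, 10,  9, 10, 10, 11,
    20, 20, 19, 20, 20, 20, 20, 20, 18,
    29, 30, 30, 29, 30, 30, 30, 30, 30,
    40, 38, 40, 40, 40, 39, 40, 40, NA,
    49, 50, 50, 49, 50, 47, 50, 49, NA),
    cols = c("head_x", "head_y", "head_z", "chest_x", "chest_y", "chest_z",
             "hips_x", "hips_y", "hips_z")),
  `3` = .ref_tab(c(
     0,  0,  1, -1,  0, 0,  -7, -83, -35,
    11, NA, 11, -1, 12, 0,  -1, -74, -36,
    19, NA, 19, -1, 19, 0,   4, -67, -35,
    30, NA, 30, -1, 31, 0,  11, -58, -34,
    38, NA, 38, -1, 39, 0,  16, -49, -32,
    50, NA, 50, -1, 52, 0,  21, -40, -29)),
  `4` = .ref_tab(c(
     1, NA,  1, -1,   1, 0,  -6,  -82, -36,
    11,  3, 11, -1,  -9, 0, -12,  -91, -34,
    20,  4, 20, -1, -20, 0, -18, -100, -32,
    29,  4, 29, -1, -29, 0, -23, -108, -29,
    42,  5, 42, -1, -38, 0, -28, -120, -24,
    50,  6, 50, -1, -51, 0, -31, -129, -19)),
  `5` = .ref_tab(c(
     0,  1,  1, -1, 0, 0,  -7,  -83, -35,
     3, 11, 11, 10, 3, 0,   3,  -87, -35,
     2, 22, 22, 21, 2, 0,  11,  -93, -36,
     1, 29, 29, 29, 1, 0,  19, -100, -37,
     1, 39, 39, 39, 1, 1,  26, -106, -39,
     2, 50, 49, 48, 3, 1,  34, -113, -43)),
  `6` = .ref_tab(c(
    16, NA, 17,  -1, 16, 1,   2, -69, -35,
    19, 10, 22, -11, 19, 1,  -4, -61, -35,
    21, 18, 29, -20, 21, 1, -10, -54, -35,
    23, 31, 37, -29, 22, 1, -18, -47, -36,
    24, 39, 45, -41, 23, 1, -25, -40, -38,
    25, 49, 54, -50, 24, 2, -32, -32, -41)),
  `7` = .ref_tab(c(
    18, NA, 18, -1, 18, -1, 4, -68, -37,
    22, 12, 19, -1, 19, 11, 4, -67, -24,
    27, 23, 17, -1, 17, 21, 3, -69, -15,
    34, 28, 16, -1, 16, 30, 3, -69,  -5,
    42, 41, 15, -1, 15, 38, 2, -70,   4,
    52, 51, 14, -1, 14, 52, 1, -71,  14)),
  `8` = .ref_tab(c(
    17, NA, 17, -2, 17,   0,  3, -68, -35,
    18,  9, 16, -1, 16, -12,  2, -70, -46,
    24, 22, 14, -1, 14, -21,  1, -71, -56,
    32, 31, 11, -1, 11, -30, -1, -74, -66,
    41, 43,  9,  0,  9, -43, -1, -76, -75,
    50, 51,  8,  2,  8, -51, -1, -78, -85)),
  `9` = .ref_tab(c(
     0, NA,  1, -1,  0,   0, 0,  5,   0,
    11, 10,  4, -1, -4, -10, 0,  1, -10,
    21, 20,  6, -2, -5, -20, 0, -1, -20,
    30, 30,  7, -2, -6, -30, 1, -2, -29,
    40, 40,  8, -3, -8, -39, 1, -4, -39,
    51, 51, 10, -4, -9, -50, 0, -6, -50)),
  `10` = .ref_tab(c(
     0, NA,  1, -1,  0, 0, -2,  1, -80,
    10, NA, 10, -1, 10, 0,  7,  3, -80,
    21, NA, 21, -1, 21, 0, 18,  5, -79,
    31, NA, 31, -1, 30, 0, 27,  7, -78,
    40, NA, 40, -1, 42, 0, 36, 10, -77,
    51, NA, 51, -1, 50, 0, 46, 13, -74))
)
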