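# body model, scenario limits, sustained-violation detection

make_trace <- function(t, angle, segment = "head", axis = "x") {
  data.frame(t = t, segment = segment, axis = axis, angle = angle)
}

test_that("the body model holds exactly 13 uniquely named segments", {
  m <- body_model()
  expect_length(m, 13)
  expect_identical(names(m), body_segments())
  expect_false(anyDuplicated(names(m)) > 0)
  expect_identical(m$head$sensor_id, "s1")
  expect_error(body_model(c(head = "a")), "missing segment")
})

test_that("update_body applies packets by timestamp and skips unknown sensors", {
  m <- body_model()
  expect_identical(update_body(m, list()), m)
  p30 <- motion_packet("s1", 0.5, quat_from_axis_angle(c(1, 0, 0), 30))
  m2 <- update_body(m, list(p30))
  expect_equal(unname(m2$head$rotation["x"]), 30, tolerance = 1e-9)
  expect_equal(unname(m2$head$correction["x"]), 30, tolerance = 1e-9)
  # later timestamp wins regardless of batch order
  p10 <- motion_packet("s1", 0.2, quat_from_axis_angle(c(1, 0, 0), 10))
  m3 <- update_body(m, list(p30, p10))
  expect_equal(unname(m3$head$rotation["x"]), 30, tolerance = 1e-9)
  expect_message(m4 <- update_body(m, list(motion_packet("ghost", 0, quat_identity()))),
                 "unknown sensor")
  expect_equal(m4$head, m$head)
  # calibration is applied to the correction channel only
  st <- capture_reference(list(head = c(30, 0, 0)))
  m5 <- update_body(m, list(p30), st)
  expect_equal(unname(m5$head$rotation["x"]), 30, tolerance = 1e-9)
  expect_equal(as.numeric(m5$head$correction), c(0, 0, 0), tolerance = 1e-9)
})

test_that("limit checks are strict and scenario presets are correct", {
  lim <- scenario_config(4)
  seg <- body_model()$head
  seg$correction <- euler_triple(29, 0, 0)
  expect_false(any(check_limits(seg, lim)))
  seg$correction <- euler_triple(30, 0, 0)
  expect_false(any(check_limits(seg, lim)))  # boundary not flagged
  seg$correction <- euler_triple(31, 0, 0)
  expect_identical(unname(check_limits(seg, lim)), c(TRUE, FALSE, FALSE))
  seg$correction <- euler_triple(0, -31, 0)
  expect_identical(unname(check_limits(seg, lim)), c(FALSE, TRUE, FALSE))
  # unmonitored segment never flags
  hand <- body_model()$hand_l
  hand$correction <- euler_triple(170, 0, 0)
  expect_false(any(check_limits(hand, lim)))

  expect_identical(sort(names(lim$segments)), c("chest", "head", "pelvis"))
  expect_true(all(unlist(lim$segments) == 30))
  expect_identical(scenario_config(0)$segments, list())
  expect_equal(scenario_config(2)$min_duration, 5)
  expect_error(scenario_config(5), "between 0 and 4")
  expect_error(scenario_config(-1), "between 0 and 4")
  expect_error(scenario_config(1.5), "between 0 and 4")
})

test_that("sustained violations are detected on constructed traces", {
  lim <- scenario_config(4)
  hz <- 60
  # 31 degrees held 10 s at 60 Hz -> exactly one event, peak 31
  tr <- make_trace(seq(0, 10 - 1 / hz, by = 1 / hz), 31)
  ev <- sustained_violation(tr, lim, rate = hz)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$peak, 31)
  expect_gte(ev$end - ev$start, lim$min_duration)
  # single-sample spike -> no events
  spike <- make_trace(seq(0, 10, by = 1 / hz), 0)
  spike$angle[300] <- 45
  expect_equal(nrow(sustained_violation(spike, lim, rate = hz)), 0)
  # never above 30 -> no events in any scenario
  calm <- make_trace(seq(0, 10, by = 1 / hz), 29.9 * sin(seq(0, 10, by = 1 / hz)))
  for (sc in 0:4)
    expect_equal(nrow(sustained_violation(calm, scenario_config(sc), rate = hz)), 0)
  # two sustained runs separated by an in-range stretch -> two events
  t2 <- seq(0, 20 - 1 / hz, by = 1 / hz)
  a2 <- ifelse(t2 < 6 | t2 >= 12, 35, 0)
  ev2 <- sustained_violation(make_trace(t2, a2), lim, rate = hz)
  expect_equal(nrow(ev2), 2)
  # timing jitter under one extra period is bridged ...
  jit <- tr
  jit$t[301:nrow(jit)] <- jit$t[301:nrow(jit)] + 0.5 / hz
  ev3 <- sustained_violation(jit, lim, rate = hz)
  expect_equal(nrow(ev3), 1)
  # ... but a fully dropped sample (a whole extra period) splits the run
  t4 <- seq(0, 12 - 1 / hz, by = 1 / hz)
  tr4 <- make_trace(t4[seq_along(t4) != 360], 31)
  ev4 <- sustained_violation(tr4, lim, rate = hz)
  expect_equal(nrow(ev4), 2)
  expect_error(sustained_violation(make_trace(c(1, 0.5), c(31, 31)), lim), "non-decreasing")
  expect_error(sustained_violation(tr[, -1], lim), "missing column")
})

test_that("event counts are invariant under time shift and in-range padding", {
  lim <- scenario_config(1)
  hz <- 60
  t <- seq(0, 30, by = 1 / hz)
  set.seed(51)
  ang <- ifelse(t > 8 & t < 16, 34, 5) + stats::rnorm(length(t), sd = 0.3)
  base <- sustained_violation(make_trace(t, ang), lim, rate = hz)
  shifted <- sustained_violation(make_trace(t + 1000, ang), lim, rate = hz)
  expect_equal(nrow(shifted), nrow(base))
  expect_equal(shifted$start - 1000, base$start, tolerance = 1e-9)
  padded <- rbind(make_trace(t, ang), make_trace(t[length(t)] + seq_len(100) / hz, 0))
  expect_equal(nrow(sustained_violation(padded, lim, rate = hz)), nrow(base))
})

test_that("doubling the sample rate moves event boundaries by under one period", {
  lim <- scenario_config(3)
  f <- function(t) ifelse(t > 2.1 & t < 9.7, 33, 0)  # continuous motion sampled twice
  t1 <- seq(0, 12, by = 1 / 30); t2 <- seq(0, 12, by = 1 / 60)
  e1 <- sustained_violation(make_trace(t1, f(t1)), lim, rate = 30)
  e2 <- sustained_violation(make_trace(t2, f(t2)), lim, rate = 60)
  expect_equal(nrow(e1), 1)
  expect_equal(nrow(e2), 1)
  expect_lte(abs(e1$start - e2$start), 1 / 30)
  expect_lte(abs(e1$end - e2$end), 1 / 30)
})

test_that("monitor_stream ties the pieces together", {
  hz <- 60
  # head pivots to 35 degrees and holds for 8 s, then returns
  prof <- motion_profile(segment = "head", motion = "pivot", target = 35,
                         ramp_time = 1, hold_time = 8, rate = hz)
  packets <- script_motion(prof)
  # map the head segment onto this sensor id
  sm <- stats::setNames(paste0("s", 1:13), body_segments())
  sm["head"] <- "head"
  res <- monitor_stream(packets, scenario_config(4), model = body_model(sm), rate = hz)
  expect_equal(nrow(res$events), 1)
  expect_equal(res$events$segment, "head")
  expect_equal(res$events$axis, "x")
  expect_equal(res$events$peak, 35, tolerance = 1e-6)
  # a calibration capture right before the ramp removes nothing here,
  # but capturing mid-hold re-zeroes the trace and kills the event
  res2 <- monitor_stream(packets, scenario_config(4), model = body_model(sm),
                         calibrate_at = 1.5, rate = hz)
  expect_equal(nrow(res2$events), 0)
})
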