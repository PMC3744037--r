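step_trace <- function(baseline = 100, step_to = 130, t_step = 85,
                       t_end = 200, dt = 0.1, bg_sd = 1) {
  t <- seq(0, t_end, by = dt)
  v <- ifelse(t < t_step, baseline, step_to)
  intensity_trace("x", t, v, background_mean = baseline,
                  background_sd = bg_sd)
}

test_that("arrival detection: sustained 20% rise marks arrival", {
  tr <- step_trace()   # threshold max(120, 100 + 5) = 120, crossed at 85 s
  arr <- detect_arrival(tr)
  expect_true(arr$detected)
  expect_equal(arr$baseline, 100)
  expect_equal(arr$threshold, 120)
  expect_equal(arr$arrival_time_s, 85, tolerance = 1e-9)
})

test_that("arrival detection: flat traces and brief spikes do not trigger", {
  flat <- intensity_trace("x", seq(0, 100, 0.1), rep(100, 1001), 100, 1)
  expect_false(detect_arrival(flat)$detected)
  # a 0.5-s spike does not satisfy the 1-s sustain requirement
  t <- seq(0, 100, 0.1)
  v <- rep(100, length(t)); v[t >= 50 & t < 50.5] <- 200
  spiky <- intensity_trace("x", t, v, 100, 1)
  expect_false(detect_arrival(spiky)$detected)
  expect_error(detect_arrival(intensity_trace("x", 0:5, rep(1, 6), 1, 1)),
               "baseline window")
})

test_that("arrival of simulated traces lands within 2 s of ground truth", {
  errs <- vapply(1:25, function(s) {
    sim <- simulate_trace(quick_config(400 + s), "v1")
    abs(detect_arrival(sim$trace)$arrival_time_s - sim$truth$arrival_time_s)
  }, numeric(1))
  expect_lt(max(errs), 2)
})

test_that("transport time handles late recording starts and missing arrivals", {
  arr <- detect_arrival(step_trace())
  expect_equal(transport_time(arr, t0_s = 0), 85, tolerance = 1e-9)
  # recording started 30 s post-injection; arrival at recording time 55 s
  tr <- step_trace(t_step = 55)
  tr$times_s <- tr$times_s + 30
  arr2 <- detect_arrival(tr)
  expect_equal(transport_time(arr2, t0_s = 0), 85, tolerance = 1e-9)
  flat <- intensity_trace("x", seq(0, 100, 0.1), rep(100, 1001), 100, 1)
  expect_identical(transport_time(detect_arrival(flat)), NA_real_)
})

test_that("segment definition follows the protocol anchors", {
  arr <- detect_arrival(step_trace())
  segs <- define_segments(arr, 1200)
  expect_equal(c(segs$arrival$start_s, segs$arrival$end_s), c(145, 245))
  expect_equal(c(segs$steady_state$start_s, segs$steady_state$end_s),
               c(600, 700))
  expect_false(segs$arrival$overlaps)

  late <- detect_arrival(step_trace(t_step = 560, t_end = 800))
  segs2 <- define_segments(late, 1200)
  expect_equal(segs2$arrival$start_s, 620)
  expect_true(segs2$arrival$overlaps)
  expect_true(segs2$steady_state$overlaps)

  verylate <- detect_arrival(step_trace(t_step = 1150, t_end = 1200))
  expect_error(define_segments(verylate, 1200), "beyond the recording")
})

test_that("detrending removes slow structure and keeps pulses", {
  t <- seq(0, 200, 0.05)
  ramp <- intensity_trace("x", t, 10 + 0.5 * t, 10, 1)
  resid <- detrend_trace(ramp)$values
  inner <- resid[t > 20 & t < 180]
  expect_lt(max(abs(inner)), 5)          # no spurious excursions above 5 sd
  const <- intensity_trace("x", t, rep(3, length(t)), 0, 1)
  expect_true(all(detrend_trace(const)$values == 0))
  expect_error(detrend_trace(intensity_trace("x", c(0, 10, 20), 1:3, 0, 1),
                             window_s = 15), "sample spacing")
})

test_that("detrended pulse amplitudes stay near the configured amplitude", {
  cfg <- quick_config(77, packet_rate_per_min = c(4, 4))
  sim <- simulate_trace(cfg, "v1")
  det <- detrend_trace(sim$trace)
  pk <- detect_packets(det, segment("arrival", 80, 180))
  expect_gt(nrow(pk), 2)
  expect_lt(abs(mean(pk$amplitude) - cfg$packet_amplitude) /
              cfg$packet_amplitude, 0.15)
})

test_that("packet frequency is count over duration in per-minute units", {
  pk <- data.frame(peak_time_s = seq_len(12), amplitude = 1, prominence = 1,
                   width_s = 1)
  expect_equal(packet_frequency(pk, segment("s", 0, 100)), 7.2)
  expect_equal(packet_frequency(pk[0, ], segment("s", 0, 100)), 0)
})

test_that("high-SNR packet counts match ground truth within one packet", {
  hits <- vapply(1:60, function(s) {
    cfg <- quick_config(900 + s, packet_rate_per_min = c(6, 6))
    sim <- simulate_trace(cfg, "v1")
    seg <- segment("arrival", 80, 180)
    pk <- detect_packets(detrend_trace(sim$trace), seg)
    truth <- sum(sim$truth$packet_times_s >= 80 & sim$truth$packet_times_s < 180)
    abs(nrow(pk) - truth) <= 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("packet velocity recovers a known front-time slope", {
  # fronts at 10.0, 11.0, 12.0 s at axial positions 2, 6, 10 mm -> 4 mm/s
  subs <- list(pulse_trace(10, 2), pulse_trace(11, 6), pulse_trace(12, 10))
  v <- packet_velocity(subs, segment("s", 0, 25))
  expect_equal(v$velocity_mm_s, 4, tolerance = 0.02)
  expect_equal(v$n_used, 1)
})

test_that("identical front times are discarded (infinite-velocity guard)", {
  subs <- list(pulse_trace(10, 2), pulse_trace(10, 6), pulse_trace(10, 10))
  v <- packet_velocity(subs, segment("s", 0, 25))
  expect_identical(v$velocity_mm_s, NA_real_)
  expect_equal(v$n_discarded, v$n_packets)
})

test_that("non-monotone fronts are discarded, monotone ones kept", {
  subs <- list(pulse_trace(c(10, 20), 2), pulse_trace(c(11, 19), 6),
               pulse_trace(c(12, 18), 10))
  v <- packet_velocity(subs, segment("s", 0, 25))
  expect_equal(v$n_packets, 2)
  expect_equal(v$n_used, 1)   # the reversed-front packet is discarded
  expect_equal(v$velocity_mm_s, 4, tolerance = 0.05)
})

test_that("front-regression and cross-correlation velocities agree", {
  cfg <- sim_config(duration_s = 190, seed = 1019,
                    arrival_time_s = c(15, 35),
                    packet_rate_per_min = c(2.5, 2.5),
                    packet_velocity_mm_s = c(1.5, 1.5))
  sim <- simulate_video(cfg)
  subs <- video_sub_traces(sim, "v1", 5)
  seg <- segment("arrival", 75, 175)
  fr <- packet_velocity(subs, seg)$velocity_mm_s
  xc <- packet_velocity(subs, seg, method = "xcorr")$velocity_mm_s
  expect_equal(fr, 1.5, tolerance = 0.1)
  expect_equal(xc, 1.5, tolerance = 0.1)
})

test_that("dominance goes to the first-arriving vessel", {
  a <- detect_arrival(step_trace(t_step = 60))
  b <- detect_arrival(step_trace(t_step = 85))
  ta <- step_trace(t_step = 60); tb <- step_trace(t_step = 85)
  dom <- classify_dominance(list(v1 = a, v2 = b), list(v1 = ta, v2 = tb),
                            0.05)
  expect_equal(dom$dominant, "v1")
  expect_equal(dom$delta_arrival_s, 25)
  expect_false(dom$tie_break)
})

test_that("arrival ties break deterministically by post-arrival intensity", {
  a <- detect_arrival(step_trace(t_step = 60, step_to = 130))
  b <- detect_arrival(step_trace(t_step = 60, step_to = 180))
  ta <- step_trace(t_step = 60, step_to = 130)
  tb <- step_trace(t_step = 60, step_to = 180)
  dom <- classify_dominance(list(v1 = a, v2 = b), list(v1 = ta, v2 = tb),
                            0.05)
  expect_true(dom$tie_break)
  expect_equal(dom$dominant, "v2")   # brighter vessel wins the tie
  # fully identical traces: deterministic fall-back to the first ROI
  dom2 <- classify_dominance(list(v1 = a, v2 = a), list(v1 = ta, v2 = ta),
                             0.05)
  expect_true(dom2$tie_break)
  expect_equal(dom2$dominant, "v1")
  flat <- intensity_trace("x", seq(0, 100, 0.1), rep(100, 1001), 100, 1)
  fa <- detect_arrival(flat)
  expect_error(classify_dominance(list(v1 = fa, v2 = fa),
                                  list(v1 = flat, v2 = flat), 0.05),
               "neither vessel")
  # single detected vessel is dominant
  dom3 <- classify_dominance(list(v1 = fa, v2 = b), list(v1 = flat, v2 = tb),
                             0.05)
  expect_equal(dom3$dominant, "v2")
})

test_that("time-shifting a trace shifts arrival and preserves packet metrics", {
  cfg <- quick_config(55, packet_rate_per_min = c(5, 5))
  sim <- simulate_trace(cfg, "v1")
  tr <- sim$trace
  shifted <- tr; shifted$times_s <- tr$times_s + 37
  expect_equal(detect_arrival(shifted)$arrival_time_s,
               detect_arrival(tr)$arrival_time_s + 37, tolerance = 1e-9)
  seg <- segment("s", 80, 180)
  seg_sh <- segment("s", 80 + 37, 180 + 37)
  pk <- detect_packets(detrend_trace(tr), seg)
  pk_sh <- detect_packets(detrend_trace(shifted), seg_sh)
  expect_equal(pk_sh$peak_time_s, pk$peak_time_s + 37, tolerance = 1e-9)
  expect_equal(packet_frequency(pk_sh, seg_sh), packet_frequency(pk, seg))
})

test_that("raising noise does not inflate detected packet counts", {
  counts <- sapply(c(2, 8), function(ns) {
    mean(vapply(1:25, function(s) {
      cfg <- quick_config(600 + s, packet_rate_per_min = c(6, 6),
                          noise_sd = ns)
      sim <- simulate_trace(cfg, "v1")
      nrow(detect_packets(detrend_trace(sim$trace), segment("s", 80, 180)))
    }, numeric(1)))
  })
  expect_lte(counts[2], counts[1] + 0.5)
})

test_that("sessions without fluorescence yield missing metrics, not crashes", {
  cfg <- sim_config(duration_s = 30, seed = 3, packet_rate_per_min = c(0, 0),
                    baseline_plateau = c(0, 0), arrival_time_s = c(5, 6))
  sim <- simulate_video(cfg)
  expect_error(analyze_session(sim$stack, sim$rois), "neither vessel")
  # one live vessel: the dead vessel carries NA metrics and a flag
  cfg2 <- sim_config(duration_s = 750, seed = 3,
                     packet_rate_per_min = c(5, 0),
                     baseline_plateau = c(150, 0),
                     arrival_time_s = c(30, 600))
  sim2 <- simulate_video(cfg2)
  s <- analyze_session(sim2$stack, sim2$rois)
  expect_equal(s$dominant, "v1")
  expect_true(is.na(s$metrics$v2$transport_time_s))
  expect_true("arrival_not_detected" %in% s$metrics$v2$flags)
  expect_false(is.na(s$metrics$v1$freq_arrival))
})

test_that("follow-up sessions keep week-0 dominance labels", {
  sim0 <- simulate_video(sim_preset("healthy", seed = 31, duration_s = 750))
  s0 <- analyze_session(sim0$stack, sim0$rois, animal_id = "a1", week = 0)
  # week-2 condition reverses nothing here, but force a check with swapped
  # arrival times so that recomputation would flip the label
  swapped <- sim_preset("healthy", seed = 32, duration_s = 750)
  swapped$arrival_time_s <- c(v1 = 85, v2 = 60)
  sim1 <- simulate_video(swapped)
  s1 <- analyze_session(sim1$stack, sim1$rois, animal_id = "a1", week = 1,
                        week0 = s0)
  expect_equal(s1$dominance_source, "week0_fixed")
  expect_equal(s1$dominant, s0$dominant)
  s1b <- analyze_session(sim1$stack, sim1$rois, animal_id = "a1", week = 1)
  expect_equal(s1b$dominance_source, "this_session")
  expect_false(s1b$dominant == s0$dominant)
})

test_that("analyze_session is deterministic", {
  sim <- simulate_video(sim_preset("healthy", seed = 41, duration_s = 750))
  s1 <- analyze_session(sim$stack, sim$rois)
  s2 <- analyze_session(sim$stack, sim$rois)
  expect_identical(s1$metrics, s2$metrics)
  expect_identical(s1$dominant, s2$dominant)
})
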