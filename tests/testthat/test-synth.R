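test_that("null process yields a constant background trace", {
  cfg <- quick_config(1, packet_rate_per_min = c(0, 0), noise_sd = 0,
                      baseline_plateau = c(0, 0))
  sim <- simulate_trace(cfg, "v1")
  expect_length(sim$truth$packet_times_s, 0)
  expect_true(all(sim$trace$values == cfg$background_level))
})

test_that("ground-truth packet counts match the renewal-rate expectation", {
  # oracle: direct count of generated event times over many seeds
  rate <- 6; dur <- 1200; t_arr <- 60
  counts <- vapply(1:300, function(s) {
    cfg <- sim_config(duration_s = dur, seed = s,
                      arrival_time_s = c(t_arr, 85))
    length(simulate_trace(cfg, "v1")$truth$packet_times_s)
  }, numeric(1))
  expected <- (dur - t_arr) * rate / 60
  # gamma renewal with shape 4: count variance ~ expected / 4
  se_mean <- sqrt(expected / 4 / length(counts))
  expect_lt(abs(mean(counts) - expected), 4 * se_mean + 0.5)
  expect_true(all(counts > expected - 4 * sqrt(expected)),
              info = "no seed falls outside renewal counting variance")
})

test_that("a single noiseless packet peaks at its ground-truth time", {
  cfg <- sim_config(duration_s = 300, seed = 1, noise_sd = 0,
                    packet_rate_per_min = c(0, 0),
                    baseline_plateau = c(0, 0), arrival_time_s = c(20, 40))
  sim <- simulate_trace(cfg, "v1")
  tr <- sim$trace
  tk <- 200
  tr$values <- tr$values + cfg$packet_amplitude *
    exp(-(tr$times_s - tk)^2 / (2 * cfg$packet_width_s^2))
  expect_lt(abs(tr$times_s[which.max(tr$values)] - tk),
            cfg$frame_interval_s / 2 + 1e-9)
})

test_that("packet times are strictly increasing and start after arrival", {
  for (s in 1:20) {
    sim <- simulate_trace(quick_config(s), "v2")
    pt <- sim$truth$packet_times_s
    expect_true(all(diff(pt) > 0))
    expect_true(all(pt >= sim$truth$arrival_time_s))
  }
})

test_that("video blob kinematics: known velocity separates sub-ROI peaks", {
  # sparse packets advected at 2 mm/s; sub-ROIs 4 mm apart pass 2.0 s apart
  cfg2 <- sim_config(duration_s = 120, seed = 7, noise_sd = 0,
                     packet_rate_per_min = c(2, 0),
                     baseline_plateau = c(0, 0), arrival_time_s = c(5, 6),
                     packet_velocity_mm_s = c(2, 2))
  sim2 <- simulate_video(cfg2)
  expect_gte(length(sim2$truth$packet_times_s$v1), 1)
  subs <- video_sub_traces(sim2, "v1", 5)
  first_tk <- sim2$truth$packet_times_s$v1[1]
  sel <- function(tr) {
    w <- tr$times_s > first_tk - 2 & tr$times_s < first_tk + 8
    tr$times_s[w][which.max(tr$values[w])]
  }
  t1 <- sel(subs[[1]]); t5 <- sel(subs[[5]])
  gap_mm <- attr(subs[[5]], "axial_mid_mm") - attr(subs[[1]], "axial_mid_mm")
  expect_equal(t5 - t1, gap_mm / 2, tolerance = 0.15)
})

test_that("zero-packet video is background everywhere", {
  cfg <- sim_config(duration_s = 30, seed = 3, noise_sd = 0,
                    packet_rate_per_min = c(0, 0),
                    baseline_plateau = c(0, 0), arrival_time_s = c(5, 6))
  sim <- simulate_video(cfg)
  expect_true(all(sim$stack$frames == round(cfg$background_level)))
})

test_that("video and trace generators share packet times from one seed", {
  cfg <- quick_config(11)
  vid <- simulate_video(cfg)
  tr1 <- simulate_trace(cfg, "v1")
  tr2 <- simulate_trace(cfg, "v2")
  expect_identical(vid$truth$packet_times_s$v1, tr1$truth$packet_times_s)
  expect_identical(vid$truth$packet_times_s$v2, tr2$truth$packet_times_s)
})

test_that("identical seeds give bit-identical generator output", {
  a <- simulate_video(quick_config(5))
  b <- simulate_video(quick_config(5))
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$truth$packet_times_s, b$truth$packet_times_s)
  ra <- simulate_retention_series(sim_config(seed = 5), frames_per_day = 40)
  rb <- simulate_retention_series(sim_config(seed = 5), frames_per_day = 40)
  expect_identical(ra$series[[3]]$stack$frames, rb$series[[3]]$stack$frames)
})

test_that("retention truth: closed-form day-0 SNR and in-window crossing", {
  cfg <- sim_config(seed = 1)
  ret <- simulate_retention_series(cfg, frames_per_day = 20)
  # amplitude/noise ratio 20 -> 20*log10(20) = 26.02 dB
  expect_equal(unname(ret$truth$snr_db_by_day[["0"]]), 20 * log10(20),
               tolerance = 1e-12)
  expect_true(all(diff(ret$truth$snr_db_by_day) < 0))
  expect_gt(ret$truth$crossing_day, 14)
  expect_lt(ret$truth$crossing_day, 21)
})

test_that("node image presets encode the week-wise enlargement", {
  cfg <- sim_config(seed = 2)
  w0 <- simulate_node_image(0, "icg", cfg)
  w1 <- simulate_node_image(1, "icg", cfg)
  w2 <- simulate_node_image(2, "icg", cfg)
  c1 <- simulate_node_image(1, "control", cfg)
  expect_equal(percent_change(w0$true_area_mm2, w1$true_area_mm2), 350)
  expect_equal(percent_change(w0$true_area_mm2, w2$true_area_mm2), 200)
  expect_equal(c1$true_area_mm2, w0$true_area_mm2)
  expect_error(simulate_node_image(3, "icg", cfg), "week")
})

test_that("noiseless unblurred ellipse area is recovered within a 1-px ring", {
  cfg <- sim_config(seed = 6)
  ni <- simulate_node_image(0, "icg", cfg, blur_sigma_px = 0, noise_sd = 0)
  a <- node_area(ni$image, ni$pixel_size_mm)
  axes_px <- cfg$node_axes_mm / cfg$node_pixel_size_mm
  ring_mm2 <- pi * (sum(axes_px) + 1) * cfg$node_pixel_size_mm^2  # ~perimeter*1px
  expect_lt(abs(a - ni$true_area_mm2), ring_mm2)
})

test_that("presets encode the study conditions", {
  h <- sim_preset("healthy")
  g <- sim_preset("gtno")
  expect_gte(diff(range(h$arrival_time_s)), 20)
  expect_equal(g$arrival_time_s[["v2"]] / h$arrival_time_s[["v2"]], 6)
  expect_true(all(g$packet_rate_per_min < h$packet_rate_per_min))
  expect_true(all(g$packet_velocity_mm_s < h$packet_velocity_mm_s))
  i1 <- sim_preset("icg_week1")
  expect_true(all(i1$arrival_time_s > h$arrival_time_s))
  expect_true(all(i1$packet_rate_per_min < h$packet_rate_per_min))
  expect_true(all(i1$packet_velocity_mm_s < h$packet_velocity_mm_s))
  i2 <- sim_preset("icg_week2")
  expect_identical(i2$arrival_time_s[["v1"]], h$arrival_time_s[["v1"]])
  expect_gt(i2$arrival_time_s[["v2"]], h$arrival_time_s[["v2"]])
  expect_identical(sim_preset("control"), sim_preset("healthy"))
  expect_identical(sim_preset("week4"), sim_preset("healthy"))
  expect_error(sim_preset("nope"), "unknown preset")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(duration_s = 50), "arrival")
  expect_error(sim_config(packet_velocity_mm_s = c(0, 1)), "velocity")
  expect_error(sim_config(interval_shape = 0), "interval_shape")
  expect_error(sim_config(roi_length_mm = 100), "frame width")
})
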