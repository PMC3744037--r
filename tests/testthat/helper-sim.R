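# Short-session config used widely in tests: arrival at 20/40 s, an
# arrival-type segment at [80, 180] fits inside a 200-s recording.
quick_config <- function(seed, ...) {
  sim_config(duration_s = 200, seed = seed,
             arrival_time_s = c(v1 = 20, v2 = 40), ...)
}

# sub-ROI traces of one vessel from a simulated video, ready for
# packet_velocity()
video_sub_traces <- function(sim, vessel = "v1", n = 5) {
  cfgpx <- sim$stack$pixel_size_mm
  lapply(subdivide_vessel_roi(sim$rois[[vessel]], n, cfgpx), function(sr) {
    tr <- extract_trace(sim$stack, sr, sim$rois$background)
    attr(tr, "axial_mid_mm") <- attr(sr, "axial_mid_mm")
    tr
  })
}

# synthetic sub-ROI trace with Gaussian pulses at known times
pulse_trace <- function(pulse_times, axial_mm, t_end = 25, dt = 0.1,
                        amp = 1, width = 0.4, bg_sd = 0.01) {
  t <- seq(0, t_end, by = dt)
  v <- rep(0, length(t))
  for (tk in pulse_times) v <- v + amp * exp(-(t - tk)^2 / (2 * width^2))
  tr <- intensity_trace(paste0("x", axial_mm), t, v,
                        background_mean = 0, background_sd = bg_sd)
  attr(tr, "axial_mid_mm") <- axial_mm
  tr
}
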