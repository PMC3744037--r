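#' Simulation configuration for synthetic NIR lymphatic imaging data
#'
#' Builds and validates the parameter set driving all synthetic-data
#' generators ([simulate_trace()], [simulate_video()],
#' [simulate_retention_series()], [simulate_node_image()]). Per-vessel
#' parameters are length-2 vectors named `v1`/`v2`; in the bundled presets
#' `v1` is the dominant (first-arrival) vessel.
#'
#' Defaults encode the standard acquisition protocol this package targets:
#' 50 ms frame interval, 20-minute sessions, and an imaging window whose
#' proximal edge sits 100 mm downstream of the injection site. Packet times
#' are parameterised at the imaging window (a packet's time is the moment it
#' enters the field of view), so the injection-to-window transit is carried
#' entirely by `arrival_time_s`.
#'
#' @param frame_interval_s Frame interval in seconds (camera exposure).
#' @param duration_s Recording duration in seconds.
#' @param pixel_size_mm Pixel size, mm per pixel.
#' @param frame_height_px,frame_width_px Frame dimensions in pixels.
#' @param vessel_row_px 0-based row indices of the two vessel centrelines.
#' @param vessel_sigma_px Gaussian cross-section SD of a vessel stripe (px).
#' @param roi_row_halfwidth_px Vessel ROI half-height in pixels (ROI spans
#'   `2*halfwidth + 1` rows around the centreline).
#' @param roi_x0_px 0-based column where the vessel ROI starts.
#' @param roi_length_mm Axial length of the vessel ROI in mm.
#' @param axial_origin_mm Distance (mm) from injection site to the ROI start.
#' @param arrival_time_s Per-vessel fluorescence arrival time at the window
#'   (seconds post-injection); this is the true transport time.
#' @param packet_rate_per_min Per-vessel mean packet rate, packets/min.
#' @param packet_velocity_mm_s Per-vessel packet advection velocity, mm/s.
#' @param packet_amplitude Peak packet excursion of the full-vessel ROI mean
#'   trace, intensity units above the local baseline.
#' @param packet_width_s Temporal Gaussian SD of a packet pulse, seconds.
#' @param interval_shape Gamma shape of inter-packet intervals (1 = Poisson;
#'   larger = more clock-like contractions).
#' @param baseline_plateau Per-vessel plateau of the saturating free-flow
#'   baseline, intensity units.
#' @param baseline_tau_s Time constant (s) of the saturating baseline rise.
#' @param background_level Pre-arrival background intensity.
#' @param noise_sd Additive Gaussian noise SD (per trace sample for
#'   [simulate_trace()]; per pixel per frame for [simulate_video()]).
#' @param noise_model `"gaussian"` (default) or `"poisson"` (shot noise with
#'   variance equal to the signal, approximated as Gaussian with
#'   signal-dependent SD).
#' @param retention_decay_days Exponential time constant (days) of
#'   injection-site tracer decay.
#' @param retention_day0_snr_ratio Day-0 ratio of injection-site amplitude to
#'   background noise SD (20 gives 26.02 dB).
#' @param retention_days Sampling days of the retention series.
#' @param node_area_scale Named numeric: projected-area scale factor of the
#'   draining lymph node at weeks 0/1/2/4 relative to baseline.
#' @param node_axes_mm Baseline node ellipse semi-axes (mm).
#' @param node_pixel_size_mm Pixel size of node microscopy images, mm.
#' @param seed Integer seed; the single source of generator randomness.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [sim_preset()] for scenario presets.
#' @export
#' @examples
#' cfg <- sim_config(duration_s = 300, seed = 7)
#' cfg$arrival_time_s
sim_config <- function(frame_interval_s = 0.05,
                       duration_s = 1200,
                       pixel_size_mm = 0.2,
                       frame_height_px = 30,
                       frame_width_px = 56,
                       vessel_row_px = c(9, 20),
                       vessel_sigma_px = 1.5,
                       roi_row_halfwidth_px = 2,
                       roi_x0_px = 3,
                       roi_length_mm = 10,
                       axial_origin_mm = 100,
                       arrival_time_s = c(v1 = 60, v2 = 85),
                       packet_rate_per_min = c(v1 = 6, v2 = 4),
                       packet_velocity_mm_s = c(v1 = 2, v2 = 1.5),
                       packet_amplitude = 40,
                       packet_width_s = 0.3,
                       interval_shape = 4,
                       baseline_plateau = c(v1 = 150, v2 = 100),
                       baseline_tau_s = 6,
                       background_level = 10,
                       noise_sd = 4,
                       noise_model = c("gaussian", "poisson"),
                       retention_decay_days = 6.5,
                       retention_day0_snr_ratio = 20,
                       retention_days = seq(0, 24, by = 2),
                       node_area_scale = c(`0` = 1, `1` = 4.5, `2` = 3, `4` = 1),
                       node_axes_mm = c(1, 0.5),
                       node_pixel_size_mm = 0.025,
                       seed = 1L) {
  noise_model <- match.arg(noise_model)
  per_vessel <- function(x, nm) {
    x <- rep_len(as.numeric(x), 2L)
    names(x) <- c("v1", "v2")
    x
  }
  cfg <- list(
    frame_interval_s = as.numeric(frame_interval_s),
    duration_s = as.numeric(duration_s),
    pixel_size_mm = as.numeric(pixel_size_mm),
    frame_height_px = as.integer(frame_height_px),
    frame_width_px = as.integer(frame_width_px),
    vessel_row_px = as.integer(rep_len(vessel_row_px, 2L)),
    vessel_sigma_px = as.numeric(vessel_sigma_px),
    roi_row_halfwidth_px = as.integer(roi_row_halfwidth_px),
    roi_x0_px = as.integer(roi_x0_px),
    roi_length_mm = as.numeric(roi_length_mm),
    axial_origin_mm = as.numeric(axial_origin_mm),
    arrival_time_s = per_vessel(arrival_time_s),
    packet_rate_per_min = per_vessel(packet_rate_per_min),
    packet_velocity_mm_s = per_vessel(packet_velocity_mm_s),
    packet_amplitude = as.numeric(packet_amplitude),
    packet_width_s = as.numeric(packet_width_s),
    interval_shape = as.numeric(interval_shape),
    baseline_plateau = per_vessel(baseline_plateau),
    baseline_tau_s = as.numeric(baseline_tau_s),
    background_level = as.numeric(background_level),
    noise_sd = as.numeric(noise_sd),
    noise_model = noise_model,
    retention_decay_days = as.numeric(retention_decay_days),
    retention_day0_snr_ratio = as.numeric(retention_day0_snr_ratio),
    retention_days = as.numeric(retention_days),
    node_area_scale = node_area_scale,
    node_axes_mm = as.numeric(node_axes_mm),
    node_pixel_size_mm = as.numeric(node_pixel_size_mm),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.finite(cfg$frame_interval_s) || cfg$frame_interval_s <= 0)
    stop("frame_interval_s must be > 0", call. = FALSE)
  if (cfg$duration_s <= 0)
    stop("duration_s must be > 0", call. = FALSE)
  if (any(cfg$packet_rate_per_min < 0))
    stop("packet_rate_per_min must be >= 0", call. = FALSE)
  if (any(cfg$packet_velocity_mm_s <= 0))
    stop("packet_velocity_mm_s must be > 0", call. = FALSE)
  if (cfg$interval_shape <= 0)
    stop("interval_shape must be > 0", call. = FALSE)
  if (cfg$packet_width_s <= 0)
    stop("packet_width_s must be > 0", call. = FALSE)
  if (cfg$noise_sd < 0)
    stop("noise_sd must be >= 0", call. = FALSE)
  if (any(cfg$arrival_time_s >= cfg$duration_s))
    stop("duration_s must exceed every arrival_time_s", call. = FALSE)
  if (cfg$retention_decay_days <= 0)
    stop("retention_decay_days must be > 0", call. = FALSE)
  # video geometry: ROI must fit inside the frame
  len_px <- round(cfg$roi_length_mm / cfg$pixel_size_mm)
  if (cfg$roi_x0_px + len_px > cfg$frame_width_px)
    stop("vessel ROI exceeds frame width", call. = FALSE)
  if (any(cfg$vessel_row_px - cfg$roi_row_halfwidth_px < 0) ||
      any(cfg$vessel_row_px + cfg$roi_row_halfwidth_px >= cfg$frame_height_px))
    stop("vessel ROI exceeds frame height", call. = FALSE)
  invisible(cfg)
}

#' Scenario presets for the synthetic-data generator
#'
#' Named experimental conditions used throughout the package's validation
#' suite. `"healthy"` is the reference two-vessel condition: the dominant
#' vessel (`v1`) arrives 25 s before the non-dominant (`v2`) and carries
#' higher packet rate, velocity, and fluorescence intensity. `"gtno"`
#' emulates topical nitric-oxide donor treatment: transport time of the
#' non-dominant vessel is 6-fold the healthy value, with both vessels'
#' packet rates and velocities depressed. `"icg_week1"` depresses all
#' function metrics in both vessels; `"icg_week2"` degrades only the
#' non-dominant vessel; `"week4"` and `"control"` equal `"healthy"`
#' (recovered function / albumin-only control).
#'
#' Absolute healthy packet rates and velocities are calibration choices in
#' the physiological range for rodent collecting lymphatics (packet rates of
#' a few per minute, velocities of order 1 mm/s); see the package vignette.
#'
#' @param name One of `"healthy"`, `"gtno"`, `"icg_week1"`, `"icg_week2"`,
#'   `"week4"`, `"control"`.
#' @param seed Integer seed stored in the returned config.
#' @param ... Further overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
#' @examples
#' sim_preset("gtno")$arrival_time_s
sim_preset <- function(name, seed = 1L, ...) {
  healthy <- list(
    arrival_time_s = c(v1 = 60, v2 = 85),
    packet_rate_per_min = c(v1 = 6, v2 = 4),
    packet_velocity_mm_s = c(v1 = 2, v2 = 1.5),
    baseline_plateau = c(v1 = 150, v2 = 100)
  )
  pars <- switch(as.character(name),
    healthy = ,
    week4 = ,
    control = healthy,
    gtno = list(
      # non-dominant transport time 6x healthy; dominant 2x; contractile
      # function (rate, velocity) depressed in both vessels
      arrival_time_s = c(v1 = 120, v2 = 510),
      packet_rate_per_min = c(v1 = 3, v2 = 1.5),
      packet_velocity_mm_s = c(v1 = 1, v2 = 0.6),
      baseline_plateau = c(v1 = 150, v2 = 100)
    ),
    icg_week1 = list(
      arrival_time_s = c(v1 = 90, v2 = 130),
      packet_rate_per_min = c(v1 = 3, v2 = 1.5),
      packet_velocity_mm_s = c(v1 = 1, v2 = 0.8),
      baseline_plateau = c(v1 = 150, v2 = 100)
    ),
    icg_week2 = list(
      arrival_time_s = c(v1 = 60, v2 = 120),
      packet_rate_per_min = c(v1 = 6, v2 = 2.5),
      packet_velocity_mm_s = c(v1 = 2, v2 = 0.9),
      baseline_plateau = c(v1 = 150, v2 = 100)
    ),
    stop("unknown preset: ", name, call. = FALSE)
  )
  do.call(sim_config, c(pars, list(seed = seed), list(...)))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  frames: %.0f x %.3f s (%.1f s total), %d x %d px @ %.3f mm/px\n",
              x$duration_s / x$frame_interval_s, x$frame_interval_s,
              x$duration_s, x$frame_height_px, x$frame_width_px,
              x$pixel_size_mm))
  cat(sprintf("  arrival: v1 %.1f s, v2 %.1f s\n",
              x$arrival_time_s[["v1"]], x$arrival_time_s[["v2"]]))
  cat(sprintf("  packets: rate %.1f/%.1f per min, velocity %.2f/%.2f mm/s, amp %.0f, width %.2f s\n",
              x$packet_rate_per_min[["v1"]], x$packet_rate_per_min[["v2"]],
              x$packet_velocity_mm_s[["v1"]], x$packet_velocity_mm_s[["v2"]],
              x$packet_amplitude, x$packet_width_s))
  cat(sprintf("  noise sd %.2f (%s), seed %d\n", x$noise_sd, x$noise_model,
              x$seed))
  invisible(x)
}
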