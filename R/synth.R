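#' Generator ground truth
#'
#' Container for the generator-side truth exported alongside every synthetic
#' data set: true packet times, velocities, arrival offsets, retention decay
#' and node areas. Each field corresponds to exactly one pipeline estimator
#' and serves as its validation oracle.
#'
#' @param ... Named truth fields (e.g. `packet_times_s`,
#'   `packet_velocity_mm_s`, `arrival_time_s`, `snr_db_by_day`,
#'   `node_area_mm2_by_week`).
#' @return An object of class `sim_truth`.
#' @export
sim_truth <- function(...) {
  x <- list(...)
  if (!is.null(x$packet_times_s)) {
    pt <- x$packet_times_s
    if (!is.list(pt)) pt <- list(pt)
    for (v in seq_along(pt)) {
      if (length(pt[[v]]) > 1 && any(diff(pt[[v]]) <= 0))
        stop("ground-truth packet times must be strictly increasing",
             call. = FALSE)
    }
  }
  structure(x, class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

# Gamma-renewal packet times on (t_arr, duration]; mean interval 60/rate s.
# shape = 1 is Poisson; larger shapes give the quasi-periodic timing of
# lymphangion contractions. Deterministic given the RNG state.
gen_packet_times <- function(rate_per_min, shape, t_arr, duration_s) {
  if (rate_per_min <= 0) return(numeric(0))
  mean_int <- 60 / rate_per_min
  span <- max(duration_s - t_arr, 0)
  n0 <- ceiling(span / mean_int + 10 * sqrt(span / mean_int + 1) + 10)
  tt <- t_arr + cumsum(stats::rgamma(n0, shape = shape,
                                     rate = shape / mean_int))
  while (tt[length(tt)] < duration_s) {
    tt <- c(tt, tt[length(tt)] +
              cumsum(stats::rgamma(n0, shape = shape,
                                   rate = shape / mean_int)))
  }
  tt[tt <= duration_s]
}

# additive noise vector for a signal; "poisson" approximates shot noise with
# a Gaussian whose SD scales as sqrt(signal / background_level) * noise_sd
sim_noise <- function(signal, noise_sd, noise_model, background_level) {
  if (noise_sd <= 0) return(numeric(length(signal)))
  if (noise_model == "poisson") {
    sd_i <- noise_sd * sqrt(pmax(signal, 0) / max(background_level, 1e-12))
    stats::rnorm(length(signal)) * sd_i
  } else {
    stats::rnorm(length(signal)) * noise_sd
  }
}

#' Simulate a per-vessel intensity trace
#'
#' Generates the mean-ROI fluorescence time course of one collecting vessel:
#' a saturating free-flow baseline
#' `plateau * (1 - exp(-(t - t_arr) / tau))` rising from a constant
#' pre-arrival background, plus Gaussian packet pulses
#' `A * exp(-(t - t_k)^2 / (2 w^2))` at gamma-renewal event times `t_k`,
#' plus additive noise. Packet times for both vessels are always drawn (in
#' fixed order `v1`, `v2`) from the seed in `config`, so traces and videos
#' generated from the same config share identical ground-truth packet times.
#'
#' @param config A [sim_config()].
#' @param vessel `"v1"` or `"v2"`.
#' @return A list with elements `trace` ([intensity_trace()]) and `truth`
#'   ([sim_truth()] with `packet_times_s`, `arrival_time_s`,
#'   `packet_velocity_mm_s`, `packet_rate_per_min`).
#' @export
#' @examples
#' sim <- simulate_trace(sim_config(duration_s = 300, seed = 2), "v1")
#' length(sim$truth$packet_times_s)
simulate_trace <- function(config, vessel = c("v1", "v2")) {
  validate_sim_config(config)
  vessel <- match.arg(vessel)
  set.seed(config$seed)
  pk <- lapply(c("v1", "v2"), function(v)
    gen_packet_times(config$packet_rate_per_min[[v]], config$interval_shape,
                     config$arrival_time_s[[v]], config$duration_s))
  names(pk) <- c("v1", "v2")

  dt <- config$frame_interval_s
  nT <- round(config$duration_s / dt)
  t <- (seq_len(nT) - 1) * dt
  arr <- config$arrival_time_s[[vessel]]
  base <- rep(config$background_level, nT)
  post <- t >= arr
  base[post] <- base[post] + config$baseline_plateau[[vessel]] *
    (1 - exp(-(t[post] - arr) / config$baseline_tau_s))
  sig <- numeric(nT)
  w <- config$packet_width_s
  for (tk in pk[[vessel]]) {
    i0 <- max(1L, floor((tk - 5 * w) / dt) + 1L)
    i1 <- min(nT, ceiling((tk + 5 * w) / dt) + 1L)
    if (i1 < i0) next
    sig[i0:i1] <- sig[i0:i1] +
      config$packet_amplitude * exp(-(t[i0:i1] - tk)^2 / (2 * w^2))
  }
  values <- base + sig +
    sim_noise(base + sig, config$noise_sd, config$noise_model,
              config$background_level)
  trace <- intensity_trace(vessel, t, values,
                           background_mean = config$background_level,
                           background_sd = config$noise_sd)
  truth <- sim_truth(
    packet_times_s = pk[[vessel]],
    arrival_time_s = arr,
    packet_velocity_mm_s = config$packet_velocity_mm_s[[vessel]],
    packet_rate_per_min = config$packet_rate_per_min[[vessel]],
    all_packet_times_s = pk
  )
  list(trace = trace, truth = truth)
}

#' Simulate a two-vessel fluorescence video stack
#'
#' Renders both collecting vessels as parallel horizontal stripes with
#' Gaussian cross-section. Each vessel carries the saturating free-flow
#' baseline of [simulate_trace()] (uniform along the axis) plus discrete
#' packets: Gaussian blobs entering the field of view at the ground-truth
#' packet times and advected left-to-right at the vessel's packet velocity.
#' Blob amplitudes are calibrated so that the full-vessel-ROI mean trace
#' reproduces `packet_amplitude`; pixel intensities are quantised to integer
#' camera counts. Extracting a full-vessel ROI trace from the output
#' reproduces [simulate_trace()] statistics (same packet times from the same
#' seed; ROI averaging reduces the per-pixel noise).
#'
#' @param config A [sim_config()].
#' @return A list with elements `stack` ([frame_stack()]), `truth`
#'   ([sim_truth()]), and `rois` (the matching [default_rois()]).
#' @export
simulate_video <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  pk <- lapply(c("v1", "v2"), function(v)
    gen_packet_times(config$packet_rate_per_min[[v]], config$interval_shape,
                     config$arrival_time_s[[v]], config$duration_s))
  names(pk) <- c("v1", "v2")

  dt <- config$frame_interval_s
  nT <- round(config$duration_s / dt)
  H <- config$frame_height_px; W <- config$frame_width_px
  t <- (seq_len(nT) - 1) * dt
  px <- config$pixel_size_mm
  hw <- config$roi_row_halfwidth_px
  len_px <- round(config$roi_length_mm / px)

  mat <- matrix(config$background_level, H * W, nT)
  rows_all <- seq_len(H)
  for (vi in 1:2) {
    v <- c("v1", "v2")[vi]
    ctr <- config$vessel_row_px[vi]                  # 0-based row
    yprof <- exp(-((rows_all - 1) - ctr)^2 / (2 * config$vessel_sigma_px^2))
    roi_rows <- (ctr - hw):(ctr + hw) + 1L           # 1-based
    ybar <- mean(yprof[roi_rows])

    # free-flow baseline, spatially uniform along the axis, scaled so the
    # vessel-ROI mean equals the configured baseline
    arr <- config$arrival_time_s[[v]]
    b_t <- numeric(nT)
    post <- t >= arr
    b_t[post] <- config$baseline_plateau[[v]] *
      (1 - exp(-(t[post] - arr) / config$baseline_tau_s))
    spat <- rep(yprof / ybar, W)
    mat <- mat + matrix(spat, ncol = 1) %*% matrix(b_t, nrow = 1)

    # packets: advected Gaussian blobs; blob peak calibrated so the
    # full-ROI mean pulse height equals packet_amplitude
    vel <- config$packet_velocity_mm_s[[v]]
    sx <- vel * config$packet_width_s / px           # axial sigma in px
    A_blob <- config$packet_amplitude * len_px / (sqrt(2 * pi) * sx * ybar)
    prow <- which(yprof > 1e-3)
    yv <- yprof[prow]
    for (tk in pk[[v]]) {
      t_lo <- tk - 4 * sx * px / vel
      t_hi <- tk + (W + 4 * sx) * px / vel
      i0 <- max(1L, floor(t_lo / dt) + 1L)
      i1 <- min(nT, ceiling(t_hi / dt) + 1L)
      if (i1 < i0) next
      for (fi in i0:i1) {
        xc <- (t[fi] - tk) * vel / px                # 0-based column
        c0 <- max(1L, floor(xc - 4 * sx) + 1L)
        c1 <- min(W, ceiling(xc + 4 * sx) + 1L)
        if (c1 < c0) next
        xvals <- exp(-(((c0:c1) - 1) - xc)^2 / (2 * sx^2))
        idx <- rep(prow, length(xvals)) +
          rep.int((((c0:c1) - 1L) * H), rep(length(prow), length(xvals))) +
          (fi - 1L) * (H * W)
        mat[idx] <- mat[idx] + A_blob * as.vector(yv %o% xvals)
      }
    }
  }
  mat <- mat + sim_noise(mat, config$noise_sd, config$noise_model,
                         config$background_level)
  frames <- array(round(pmax(mat, 0)), c(H, W, nT))

  truth <- sim_truth(
    packet_times_s = pk,
    arrival_time_s = config$arrival_time_s,
    packet_velocity_mm_s = config$packet_velocity_mm_s,
    packet_rate_per_min = config$packet_rate_per_min,
    dominant = names(which.min(config$arrival_time_s))
  )
  list(stack = frame_stack(frames, dt, px),
       truth = truth,
       rois = default_rois(config))
}

#' Simulate an injection-site retention image series
#'
#' One short stack per sampling day. The injection-site signal is a uniform
#' patch whose amplitude decays as `exp(-day / retention_decay_days)` over a
#' constant-statistics noisy background; the day-0 amplitude is
#' `retention_day0_snr_ratio * noise_sd`. With the default calibration
#' (ratio 20, decay constant 6.5 days) the analytic 3 dB visibility crossing
#' falls at 17.2 days, i.e. the tracer stays visible for more than two weeks.
#'
#' @param config A [sim_config()].
#' @param frames_per_day Frames in each daily stack (default 240, i.e. 12 s).
#' @return A list with `series` (list of `list(day=, stack=)`), `rois`
#'   (injection-site and background ROIs), and `truth` ([sim_truth()] with
#'   `snr_db_by_day` and the analytic `crossing_day`).
#' @export
simulate_retention_series <- function(config, frames_per_day = 240L) {
  validate_sim_config(config)
  set.seed(config$seed)
  days <- config$retention_days
  tau <- config$retention_decay_days
  A0 <- config$retention_day0_snr_ratio * config$noise_sd
  H <- 30L; W <- 40L
  inj <- roi_rect("injection_site", "injection_site", 24, 10, 36, 20)
  bg <- roi_rect("background", "background", 2, 2, 14, 26)
  inj_mask <- roi_mask(inj, c(H, W))

  series <- lapply(days, function(d) {
    amp <- A0 * exp(-d / tau)
    sig <- matrix(config$background_level, H, W)
    sig[inj_mask] <- sig[inj_mask] + amp
    base <- array(sig, c(H, W, frames_per_day))
    base <- base + sim_noise(base, config$noise_sd, config$noise_model,
                             config$background_level)
    list(day = d,
         stack = frame_stack(round(pmax(base, 0)), config$frame_interval_s,
                             config$pixel_size_mm))
  })
  ratio_by_day <- config$retention_day0_snr_ratio * exp(-days / tau)
  truth <- sim_truth(
    snr_db_by_day = stats::setNames(20 * log10(ratio_by_day),
                                    as.character(days)),
    crossing_day = tau * log(config$retention_day0_snr_ratio / 10^(3 / 20)),
    decay_days = tau
  )
  list(series = series, rois = list(injection = inj, background = bg),
       truth = truth)
}

#' Simulate a lymph-node microscopy image
#'
#' An ellipse of known projected area on a textured background, blurred and
#' noised. Tracer-group (ICG) presets scale the baseline area by the
#' week-dependent factors in `config$node_area_scale` (defaults 1.0, 4.5,
#' 3.0, 1.0 at weeks 0/1/2/4, i.e. +350% at week 1 and +200% at week 2);
#' control nodes stay at baseline at all weeks.
#'
#' @param week One of 0, 1, 2, 4.
#' @param group `"icg"` (tracer) or `"control"`.
#' @param config A [sim_config()].
#' @param blur_sigma_px,noise_sd Image blur SD (px) and additive noise SD on
#'   the unit-intensity scale; set both to 0 for an exact ellipse.
#' @return A list with `image` (numeric matrix in `[0, 1]`),
#'   `true_area_mm2`, `pixel_size_mm`, `week`, `group`.
#' @export
simulate_node_image <- function(week, group = c("icg", "control"), config,
                                blur_sigma_px = 1.5, noise_sd = 0.03) {
  group <- match.arg(tolower(group), c("icg", "control"))
  if (!week %in% c(0, 1, 2, 4))
    stop("week must be one of 0, 1, 2, 4", call. = FALSE)
  validate_sim_config(config)
  scale <- if (group == "icg") {
    s <- config$node_area_scale[[as.character(week)]]
    if (is.null(s)) stop("no node_area_scale entry for week ", week,
                         call. = FALSE)
    s
  } else 1
  set.seed(config$seed + 1000L * as.integer(week) +
             if (group == "control") 7L else 0L)
  px <- config$node_pixel_size_mm
  H <- W <- 200L
  a_px <- config$node_axes_mm[1] * sqrt(scale) / px
  b_px <- config$node_axes_mm[2] * sqrt(scale) / px
  if (a_px >= W / 2 - 5 || b_px >= H / 2 - 5)
    stop("node ellipse does not fit in the image", call. = FALSE)
  cx <- (W - 1) / 2 + stats::runif(1, -5, 5)
  cy <- (H - 1) / 2 + stats::runif(1, -5, 5)
  th <- stats::runif(1, 0, pi)
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), times = W), H, W)
  u <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
  v <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
  inside <- (u / a_px)^2 + (v / b_px)^2 <= 1
  img <- 0.15 + 0.6 * inside
  if (noise_sd > 0) img <- img + stats::rnorm(H * W, 0, noise_sd / 2)
  if (blur_sigma_px > 0)
    img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                             sigma = blur_sigma_px))
  if (noise_sd > 0) img <- img + stats::rnorm(H * W, 0, noise_sd)
  img <- pmin(pmax(img, 0), 1)
  list(image = img,
       true_area_mm2 = pi * prod(config$node_axes_mm) * scale,
       pixel_size_mm = px, week = week, group = group)
}
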