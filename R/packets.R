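#' Analysis parameters for the packet pipeline
#'
#' Tunable parameters of the per-session quantification, with defaults
#' reproducing the standard protocol constants: a 20% intensity rise marks
#' fluorescence arrival (with an absolute noise floor), analysis segments
#' are 100 s long, the steady-state segment starts 10 min post-injection,
#' and the visibility limit is 3 dB.
#'
#' @param baseline_window_s Pre-arrival window for the arrival baseline (s).
#' @param rise_factor Relative arrival threshold: `rise_factor * baseline`.
#' @param arrival_sd_mult Absolute arrival floor:
#'   `baseline + arrival_sd_mult * background_sd`.
#' @param sustain_s Time the trace must stay above threshold to count as
#'   arrived (s).
#' @param onset_fit_s Window after the threshold crossing used for the
#'   tangent back-extrapolation of the arrival onset (s).
#' @param segment_length_s Length of both analysis segments (s).
#' @param arrival_delay_s Arrival segment starts this long after per-vessel
#'   fluorescence arrival (s).
#' @param steady_start_s Steady-state segment start, seconds post-injection.
#' @param detrend_window_s Running-median window of [detrend_trace()] (s).
#' @param prominence_sd_mult `k`: packet prominence floor in background SDs.
#' @param prominence_range_frac `f`: packet prominence floor as a fraction
#'   of the segment dynamic range; the floor is the max of the two.
#' @param min_separation_s Minimum packet peak separation (s).
#' @param smooth_s Gaussian pre-smoothing SD before peak detection (s);
#'   0 disables.
#' @param n_subrois Sub-ROIs used for packet velocity.
#' @param velocity_r2_min Minimum front-regression R^2 to keep a packet.
#' @param velocity_window_s Maximum half-width of the per-sub-ROI front
#'   search window around a reference peak (s).
#' @param snr_limit_db Visibility limit (dB).
#' @param snr_mode `"amplitude"` or `"power"` dB convention.
#' @param alpha Significance level of downstream tests.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(baseline_window_s = 10,
                            rise_factor = 1.2,
                            arrival_sd_mult = 5,
                            sustain_s = 1,
                            onset_fit_s = 2,
                            segment_length_s = 100,
                            arrival_delay_s = 60,
                            steady_start_s = 600,
                            detrend_window_s = 30,
                            prominence_sd_mult = 5,
                            prominence_range_frac = 0.1,
                            min_separation_s = 1,
                            smooth_s = 0.15,
                            n_subrois = 5,
                            velocity_r2_min = 0.8,
                            velocity_window_s = 10,
                            snr_limit_db = 3,
                            snr_mode = "amplitude",
                            alpha = 0.05) {
  cfg <- as.list(environment())
  class(cfg) <- "analysis_config"
  cfg
}

#' Detect fluorescence arrival in a vessel trace
#'
#' Baseline is the median of the first `baseline_window_s` seconds; the
#' arrival threshold is `max(rise_factor * baseline,
#' baseline + arrival_sd_mult * background_sd)` — the relative 20% rise of
#' the standard protocol, guarded by an absolute noise floor so near-zero
#' baselines cannot trigger on noise. Detection requires the trace to
#' exceed the threshold continuously for at least `sustain_s` seconds; the
#' reported arrival time is then refined by tangent back-extrapolation: a
#' line fitted over `onset_fit_s` seconds from the crossing is intersected
#' with the baseline, correcting the systematic lag a finite rise threshold
#' has behind the true fluorescence onset (the correction is skipped for
#' non-rising fits, e.g. an ideal step, and capped at `2 * onset_fit_s`).
#'
#' @param trace An [intensity_trace()] with at least `baseline_window_s`
#'   seconds of pre-arrival data.
#' @param config An [analysis_config()].
#' @return A list of class `arrival_result`: `arrival_time_s`, `baseline`,
#'   `threshold`, `detected`.
#' @export
detect_arrival <- function(trace, config = analysis_config()) {
  stopifnot(inherits(trace, "intensity_trace"))
  t <- trace$times_s; v <- trace$values
  t_rel <- t - t[1]
  if (length(t) < 2 || t_rel[length(t_rel)] < config$baseline_window_s)
    stop("trace shorter than the baseline window", call. = FALSE)
  base_idx <- t_rel < config$baseline_window_s
  baseline <- stats::median(v[base_idx])
  floor_abs <- if (is.finite(trace$background_sd))
    baseline + config$arrival_sd_mult * trace$background_sd else -Inf
  threshold <- max(config$rise_factor * baseline, floor_abs)
  dt <- trace_dt(trace)
  m <- max(1L, round(config$sustain_s / dt))
  above <- v > threshold
  # first index from which `above` holds for m consecutive samples
  run <- stats::filter(as.numeric(above), rep(1, m), sides = 1)
  hit <- which(run == m)
  arrival <- NA_real_
  if (length(hit)) {
    i_cross <- hit[1] - m + 1L
    t_cross <- t[i_cross]
    arrival <- t_cross
    # tangent back-extrapolation to baseline
    sel <- which(t >= t_cross & t <= t_cross + config$onset_fit_s)
    if (length(sel) >= 3) {
      fit <- stats::lm.fit(cbind(1, t[sel]), v[sel])
      b <- fit$coefficients[2]
      if (is.finite(b) && b > 0) {
        t_onset <- (baseline - fit$coefficients[1]) / b
        if (t_onset < t_cross &&
            t_cross - t_onset <= 2 * config$onset_fit_s)
          arrival <- unname(t_onset)
      }
    }
  }
  res <- list(baseline = baseline, threshold = threshold,
              detected = length(hit) > 0,
              arrival_time_s = arrival)
  class(res) <- "arrival_result"
  res
}

#' @export
print.arrival_result <- function(x, ...) {
  if (x$detected)
    cat(sprintf("<arrival_result> arrival %.2f s (baseline %.2f, threshold %.2f)\n",
                x$arrival_time_s, x$baseline, x$threshold))
  else
    cat(sprintf("<arrival_result> not detected (baseline %.2f, threshold %.2f)\n",
                x$baseline, x$threshold))
  invisible(x)
}

#' Tracer transport time
#'
#' Time for the tracer bolus to travel from the injection site to the
#' imaging window: the detected arrival time expressed relative to
#' injection (`t0_s` accounts for recordings started after injection).
#' Undetected arrival yields `NA` (a missing metric), never zero.
#'
#' @param arrival An `arrival_result`.
#' @param t0_s Recording start relative to injection (s).
#' @return Transport time in seconds, or `NA_real_`.
#' @export
transport_time <- function(arrival, t0_s = 0) {
  stopifnot(inherits(arrival, "arrival_result"))
  if (!arrival$detected) return(NA_real_)
  arrival$arrival_time_s + t0_s
}

#' Define the arrival and steady-state analysis segments
#'
#' Arrival segment: `[arrival + arrival_delay_s, + segment_length_s]`
#' (default 60 s after per-vessel fluorescence arrival, 100 s long).
#' Steady-state segment: `[steady_start_s, + segment_length_s]` anchored to
#' injection time (default minute 10), regardless of arrival. Segments
#' extending past the end of the trace are truncated and flagged; an
#' arrival segment lying entirely beyond the recording is an error;
#' overlapping segments are allowed and flagged.
#'
#' @param arrival A detected `arrival_result`.
#' @param trace_end_s End of the recording, seconds post-injection.
#' @param config An [analysis_config()].
#' @return List with [segment()]s `arrival` and `steady_state`.
#' @export
define_segments <- function(arrival, trace_end_s,
                            config = analysis_config()) {
  stopifnot(inherits(arrival, "arrival_result"))
  if (!arrival$detected)
    stop("cannot define segments without a detected arrival", call. = FALSE)
  a0 <- arrival$arrival_time_s + config$arrival_delay_s
  a1 <- a0 + config$segment_length_s
  s0 <- config$steady_start_s
  s1 <- s0 + config$segment_length_s
  if (a0 >= trace_end_s)
    stop("arrival segment lies entirely beyond the recording", call. = FALSE)
  trunc_a <- a1 > trace_end_s
  trunc_s <- s1 > trace_end_s
  if (s0 >= trace_end_s)
    stop("steady-state segment lies entirely beyond the recording",
         call. = FALSE)
  overlap <- a0 < s1 && s0 < a1
  list(
    arrival = segment("arrival", a0, min(a1, trace_end_s),
                      truncated = trunc_a, overlaps = overlap),
    steady_state = segment("steady_state", s0, min(s1, trace_end_s),
                           truncated = trunc_s, overlaps = overlap)
  )
}

#' Remove the slow baseline from a trace
#'
#' Subtracts a running-median baseline (default window 30 s), separating
#' pulsatile packet activity from the saturating free-flow rise. Background
#' statistics are carried over unchanged.
#'
#' @param trace An [intensity_trace()].
#' @param window_s Running-median window in seconds; must exceed twice the
#'   sample spacing.
#' @return A detrended [intensity_trace()] (attribute `detrended = TRUE`).
#' @export
detrend_trace <- function(trace, window_s = 30) {
  stopifnot(inherits(trace, "intensity_trace"))
  dt <- trace_dt(trace)
  if (!is.finite(dt) || window_s <= 2 * dt)
    stop("window_s must exceed twice the sample spacing", call. = FALSE)
  k <- round(window_s / dt)
  if (k %% 2 == 0) k <- k + 1
  k <- min(k, length(trace$values) - (1 - length(trace$values) %% 2))
  base <- stats::runmed(trace$values, k, endrule = "median")
  out <- intensity_trace(trace$roi_label, trace$times_s,
                         trace$values - base,
                         background_mean = trace$background_mean,
                         background_sd = trace$background_sd)
  attr(out, "detrended") <- TRUE
  out
}

#' Detect packets in an analysis segment
#'
#' Packets are transient intensity pulses produced by lymphangion
#' contractions. On a detrended trace, packets are strict local maxima
#' (after optional Gaussian pre-smoothing) with prominence at least
#' `max(k * background_sd, f * segment dynamic range)` and minimum peak
#' separation `min_separation_s` — see [find_peaks()] for the exact rules.
#' Deterministic for fixed input; an empty result is valid.
#'
#' @param trace A detrended [intensity_trace()] (see [detrend_trace()]).
#' @param segment A [segment()] within the trace support.
#' @param config An [analysis_config()].
#' @return Data frame of class `packet_set`: `peak_time_s`, `amplitude`,
#'   `prominence`, `width_s`.
#' @export
detect_packets <- function(trace, segment, config = analysis_config()) {
  stopifnot(inherits(trace, "intensity_trace"), inherits(segment, "segment"))
  idx <- which(segment_index(trace, segment))
  empty <- data.frame(peak_time_s = numeric(0), amplitude = numeric(0),
                      prominence = numeric(0), width_s = numeric(0))
  class(empty) <- c("packet_set", "data.frame")
  if (length(idx) < 3) return(empty)
  dt <- trace_dt(trace)
  v <- trace$values[idx]
  if (config$smooth_s > 0) v <- gaussian_smooth(v, config$smooth_s / dt)
  floor_sd <- if (is.finite(trace$background_sd))
    config$prominence_sd_mult * trace$background_sd else 0
  floor_rng <- config$prominence_range_frac * diff(range(v))
  prom_min <- max(floor_sd, floor_rng, .Machine$double.eps)
  sep <- max(1L, round(config$min_separation_s / dt))
  pk <- find_peaks(v, min_prominence = prom_min, min_separation = sep)
  if (!nrow(pk)) return(empty)
  width_s <- vapply(seq_len(nrow(pk)), function(j) {
    p <- pk$index[j]
    half <- pk$value[j] - pk$prominence[j] / 2
    l <- p; while (l > 1 && v[l] > half) l <- l - 1
    r <- p; while (r < length(v) && v[r] > half) r <- r + 1
    (r - l) * dt
  }, numeric(1))
  out <- data.frame(peak_time_s = trace$times_s[idx[pk$index]],
                    amplitude = pk$value,
                    prominence = pk$prominence,
                    width_s = width_s)
  class(out) <- c("packet_set", "data.frame")
  out
}

#' Packet frequency over a segment
#'
#' Number of detected packets divided by the segment duration, in
#' packets/min.
#'
#' @param packets A `packet_set` from [detect_packets()].
#' @param segment The [segment()] the packets were detected in.
#' @return Packets per minute.
#' @export
packet_frequency <- function(packets, segment) {
  stopifnot(inherits(segment, "segment"))
  dur <- segment_duration_s(segment)
  if (dur <= 0) stop("segment duration must be > 0", call. = FALSE)
  nrow(packets) * 60 / dur
}

#' Packet velocity by multi-sub-ROI front regression
#'
#' Estimates the advection velocity of packets through the field of view.
#' Packets are detected in the middle sub-ROI trace (the reference); for
#' each reference packet, the pulse peak time at every sub-ROI is located
#' within a window around the reference peak and refined by parabolic
#' sub-frame interpolation; velocity is the least-squares slope of axial
#' position (mm) against front time (s). Packets with non-monotone front
#' times or regression R^2 below `velocity_r2_min` are discarded (and
#' counted); the segment value is the median over surviving packets.
#'
#' `method = "xcorr"` selects an alternative packet-free estimator: the
#' whole-segment cross-correlation lag between adjacent sub-ROI traces
#' (parabolically interpolated below the frame interval) converted to
#' velocity by the known sub-ROI spacing, median-aggregated over adjacent
#' pairs. It needs no per-packet bookkeeping and is useful as a
#' cross-check when individual packets are hard to isolate.
#'
#' @param sub_traces List of >= 3 [intensity_trace()]s from
#'   [subdivide_vessel_roi()] sub-ROIs (ordered injection-proximal to
#'   distal), each carrying an `axial_mid_mm` attribute. Raw traces are
#'   detrended internally.
#' @param segment A [segment()].
#' @param config An [analysis_config()].
#' @param method `"front_regression"` (default) or `"xcorr"`.
#' @return List of class `velocity_result`: `velocity_mm_s` (median; `NA`
#'   if no packet usable), `n_packets`, `n_used`, `n_discarded`,
#'   `per_packet` data frame.
#' @export
packet_velocity <- function(sub_traces, segment,
                            config = analysis_config(),
                            method = c("front_regression", "xcorr")) {
  method <- match.arg(method)
  stopifnot(is.list(sub_traces), length(sub_traces) >= 3)
  pos <- vapply(sub_traces, function(tr) {
    p <- attr(tr, "axial_mid_mm")
    if (is.null(p)) NA_real_ else p
  }, numeric(1))
  if (anyNA(pos))
    stop("sub-traces must carry axial_mid_mm attributes", call. = FALSE)
  det <- lapply(sub_traces, function(tr) {
    d <- detrend_trace(tr, config$detrend_window_s)
    if (config$smooth_s > 0) {
      dt <- trace_dt(d)
      d$values <- gaussian_smooth(d$values, config$smooth_s / dt)
    }
    d
  })
  if (method == "xcorr") return(velocity_xcorr(det, pos, segment))
  ref_i <- ceiling(length(det) / 2)
  ref <- det[[ref_i]]
  cfg_ref <- config; cfg_ref$smooth_s <- 0   # reference already smoothed
  pk <- detect_packets(ref, segment, cfg_ref)
  per <- data.frame(peak_time_s = numeric(0), velocity_mm_s = numeric(0),
                    r_squared = numeric(0), kept = logical(0))
  if (nrow(pk)) {
    dt <- trace_dt(ref)
    gaps <- diff(pk$peak_time_s)
    for (j in seq_len(nrow(pk))) {
      t_ref <- pk$peak_time_s[j]
      left_gap <- if (j > 1) gaps[j - 1] / 2 else Inf
      right_gap <- if (j < nrow(pk)) gaps[j] / 2 else Inf
      w_l <- min(config$velocity_window_s, left_gap)
      w_r <- min(config$velocity_window_s, right_gap)
      fronts <- vapply(det, function(tr) {
        sel <- which(tr$times_s >= t_ref - w_l & tr$times_s <= t_ref + w_r)
        if (length(sel) < 3) return(NA_real_)
        vv <- tr$values[sel]
        m <- which.max(vv)
        if (m == 1 || m == length(vv)) return(tr$times_s[sel[m]])
        # parabolic sub-frame interpolation through the 3 samples at the max
        y1 <- vv[m - 1]; y2 <- vv[m]; y3 <- vv[m + 1]
        den <- y1 - 2 * y2 + y3
        off <- if (den >= 0) 0 else 0.5 * (y1 - y3) / den
        tr$times_s[sel[m]] + off * trace_dt(tr)
      }, numeric(1))
      ok <- is.finite(fronts)
      kept <- FALSE; vel <- NA_real_; r2 <- NA_real_
      if (sum(ok) >= 2) {
        ft <- fronts[ok]; xp <- pos[ok]
        if (all(diff(ft) > 0) && stats::var(ft) > 0) {
          fit <- stats::lm.fit(cbind(1, ft), xp)
          vel <- fit$coefficients[2]
          r2 <- 1 - sum(fit$residuals^2) / sum((xp - mean(xp))^2)
          kept <- is.finite(vel) && vel > 0 && r2 >= config$velocity_r2_min
        }
      }
      per <- rbind(per, data.frame(peak_time_s = t_ref, velocity_mm_s = vel,
                                   r_squared = r2, kept = kept))
    }
  }
  used <- per$velocity_mm_s[per$kept]
  res <- list(
    velocity_mm_s = if (length(used)) stats::median(used) else NA_real_,
    n_packets = nrow(per),
    n_used = length(used),
    n_discarded = nrow(per) - length(used),
    per_packet = per
  )
  class(res) <- "velocity_result"
  res
}

# whole-segment cross-correlation velocity: per adjacent sub-ROI pair, the
# lag maximising the cross-correlation of the detrended segment traces,
# refined by parabolic interpolation; velocity = spacing / lag
velocity_xcorr <- function(det, pos, segment) {
  dt <- trace_dt(det[[1]])
  segvals <- lapply(det, function(tr) {
    v <- tr$values[segment_index(tr, segment)]
    v - mean(v)
  })
  pair_v <- vapply(seq_len(length(det) - 1), function(i) {
    a <- segvals[[i]]; b <- segvals[[i + 1]]
    n <- min(length(a), length(b))
    if (n < 10) return(NA_real_)
    cc <- stats::ccf(b[1:n], a[1:n], lag.max = floor(n / 3),
                     plot = FALSE, demean = FALSE)
    k <- which.max(cc$acf)
    lag <- cc$lag[k]
    if (k > 1 && k < length(cc$acf)) {
      y1 <- cc$acf[k - 1]; y2 <- cc$acf[k]; y3 <- cc$acf[k + 1]
      den <- y1 - 2 * y2 + y3
      if (den < 0) lag <- lag + 0.5 * (y1 - y3) / den
    }
    lag_s <- lag * dt
    if (lag_s <= 0) return(NA_real_)
    (pos[i + 1] - pos[i]) / lag_s
  }, numeric(1))
  used <- pair_v[is.finite(pair_v) & pair_v > 0]
  res <- list(
    velocity_mm_s = if (length(used)) stats::median(used) else NA_real_,
    n_packets = length(pair_v), n_used = length(used),
    n_discarded = length(pair_v) - length(used),
    per_packet = data.frame(pair = seq_along(pair_v),
                            velocity_mm_s = pair_v,
                            kept = is.finite(pair_v) & pair_v > 0)
  )
  class(res) <- "velocity_result"
  res
}

#' @export
print.velocity_result <- function(x, ...) {
  cat(sprintf("<velocity_result> %.3f mm/s (median of %d packets, %d discarded)\n",
              x$velocity_mm_s, x$n_used, x$n_discarded))
  invisible(x)
}

#' Classify the dominant collecting vessel
#'
#' The vessel in which fluorescence arrives first is dominant, the other
#' non-dominant. If the arrival-time difference is below one frame interval
#' the tie is broken by the higher mean intensity over the first 100 s
#' post-arrival (the dominant vessel nearly always produces higher
#' intensities); a fully unresolvable tie falls back deterministically to
#' the first ROI and is flagged. If only one vessel shows arrival, it is
#' dominant; neither arriving is an error.
#'
#' @param arrivals Named list of two `arrival_result`s.
#' @param traces Named list of the two corresponding [intensity_trace()]s.
#' @param frame_interval_s Frame interval (s) used for the tie threshold.
#' @return List of class `dominance_result`: `dominant`, `non_dominant`,
#'   `tie_break` (logical), `delta_arrival_s`.
#' @export
classify_dominance <- function(arrivals, traces, frame_interval_s) {
  stopifnot(length(arrivals) == 2, length(traces) == 2)
  labs <- names(arrivals)
  if (is.null(labs)) labs <- c("v1", "v2")
  det <- vapply(arrivals, `[[`, TRUE, "detected")
  if (!any(det)) stop("fluorescence arrival detected in neither vessel",
                      call. = FALSE)
  tie_break <- FALSE
  if (sum(det) == 1) {
    dom <- labs[which(det)]
    delta <- NA_real_
  } else {
    at <- vapply(arrivals, `[[`, 0, "arrival_time_s")
    delta <- abs(at[1] - at[2])
    if (delta >= frame_interval_s) {
      dom <- labs[which.min(at)]
    } else {
      tie_break <- TRUE
      post_mean <- vapply(seq_along(traces), function(i) {
        tr <- traces[[i]]
        sel <- tr$times_s >= at[i] & tr$times_s < at[i] + 100
        if (!any(sel)) -Inf else mean(tr$values[sel])
      }, numeric(1))
      dom <- if (post_mean[2] > post_mean[1]) labs[2] else labs[1]
    }
  }
  res <- list(dominant = dom, non_dominant = setdiff(labs, dom),
              tie_break = tie_break, delta_arrival_s = unname(delta))
  class(res) <- "dominance_result"
  res
}

vessel_metrics <- function(transport_time_s = NA_real_,
                           freq_arrival = NA_real_, freq_steady = NA_real_,
                           vel_arrival = NA_real_, vel_steady = NA_real_,
                           flags = character(0)) {
  structure(list(transport_time_s = transport_time_s,
                 freq_arrival = freq_arrival, freq_steady = freq_steady,
                 vel_arrival = vel_arrival, vel_steady = vel_steady,
                 flags = flags),
            class = "vessel_metrics")
}

#' @export
print.vessel_metrics <- function(x, ...) {
  cat(sprintf("  transport %.1f s | freq %.2f / %.2f per min | vel %.3f / %.3f mm/s (arrival / steady)\n",
              x$transport_time_s, x$freq_arrival, x$freq_steady,
              x$vel_arrival, x$vel_steady))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result> animal %s, week %s, group %s\n",
              x$animal_id, x$week, x$group))
  cat(sprintf("  dominant: %s (%s)\n", x$dominant, x$dominance_source))
  for (v in names(x$metrics)) {
    cat(sprintf(" %s%s:\n", v, if (v == x$dominant) " [dominant]" else ""))
    print(x$metrics[[v]])
  }
  invisible(x)
}

#' Analyze a full imaging session
#'
#' End-to-end composition of the per-session pipeline: per-vessel trace
#' extraction, arrival detection, segment definition, detrending, packet
#' detection, packet frequency, and multi-sub-ROI packet velocity, plus
#' dominance classification. For follow-up sessions (`week > 0`) with a
#' supplied week-0 result, dominance labels are copied from week 0 rather
#' than recomputed, regardless of the follow-up transport times. Stage
#' failures for one vessel (e.g. no detectable fluorescence) produce
#' missing metrics (`NA`) with flags, never zeros and never a crash.
#'
#' @param stack A [frame_stack()].
#' @param rois ROI list with two vessel ROIs and one background ROI (e.g.
#'   from [default_rois()] or [read_rois()]).
#' @param config An [analysis_config()].
#' @param animal_id,week,group Session metadata.
#' @param week0 Optional week-0 `session_result` fixing dominance labels.
#' @return A `session_result`: `metrics` (named list of `vessel_metrics`),
#'   `dominant`, `dominance_source`, metadata, and per-vessel `arrivals`.
#' @export
analyze_session <- function(stack, rois, config = analysis_config(),
                            animal_id = "a1", week = 0, group = "treatment",
                            week0 = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  validate_rois(rois, dim = dim(stack$frames))
  purposes <- vapply(rois, `[[`, "", "purpose")
  vrois <- rois[purposes == "vessel"][1:2]
  bg <- rois[[which(purposes == "background")]]
  labs <- vapply(vrois, `[[`, "", "label")
  trace_end <- max(stack_times(stack)) + stack$frame_interval_s

  traces <- lapply(vrois, extract_trace, stack = stack, background_roi = bg,
                   background_window_s = config$baseline_window_s)
  names(traces) <- labs
  arrivals <- lapply(traces, detect_arrival, config = config)
  names(arrivals) <- labs

  metrics <- lapply(labs, function(v) {
    arr <- arrivals[[v]]
    if (!arr$detected)
      return(vessel_metrics(flags = "arrival_not_detected"))
    flags <- character(0)
    tt <- transport_time(arr, t0_s = stack$t0_s)
    segs <- tryCatch(define_segments(arr, trace_end, config),
                     error = function(e) NULL)
    if (is.null(segs))
      return(vessel_metrics(transport_time_s = tt,
                            flags = "segments_outside_recording"))
    if (segs$arrival$truncated || segs$steady_state$truncated)
      flags <- c(flags, "segment_truncated")
    if (segs$arrival$overlaps) flags <- c(flags, "segments_overlap")
    det <- detrend_trace(traces[[v]], config$detrend_window_s)
    pk_a <- detect_packets(det, segs$arrival, config)
    pk_s <- detect_packets(det, segs$steady_state, config)
    vroi <- vrois[[which(labs == v)]]
    sub_traces <- lapply(
      subdivide_vessel_roi(vroi, config$n_subrois, stack$pixel_size_mm),
      function(sr) {
        tr <- extract_trace(stack, sr, bg, config$baseline_window_s)
        attr(tr, "axial_mid_mm") <- attr(sr, "axial_mid_mm")
        tr
      })
    vel_a <- packet_velocity(sub_traces, segs$arrival, config)
    vel_s <- packet_velocity(sub_traces, segs$steady_state, config)
    if (vel_a$n_discarded + vel_s$n_discarded > 0)
      flags <- c(flags, sprintf("velocity_discarded_%d",
                                vel_a$n_discarded + vel_s$n_discarded))
    vessel_metrics(
      transport_time_s = tt,
      freq_arrival = packet_frequency(pk_a, segs$arrival),
      freq_steady = packet_frequency(pk_s, segs$steady_state),
      vel_arrival = vel_a$velocity_mm_s,
      vel_steady = vel_s$velocity_mm_s,
      flags = flags
    )
  })
  names(metrics) <- labs

  if (week > 0 && !is.null(week0)) {
    stopifnot(inherits(week0, "session_result"))
    dominant <- week0$dominant
    dominance_source <- "week0_fixed"
  } else {
    dom <- classify_dominance(arrivals, traces, stack$frame_interval_s)
    dominant <- dom$dominant
    dominance_source <- "this_session"
  }
  structure(
    list(animal_id = animal_id, week = week, group = group,
         metrics = metrics, dominant = dominant,
         dominance_source = dominance_source, arrivals = arrivals),
    class = "session_result"
  )
}
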