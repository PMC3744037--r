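#' Construct a calibrated frame stack
#'
#' The raw observable of the pipeline: a time-ordered stack of 2-D intensity
#' frames with temporal and spatial calibration. Frame `i` (1-based) is
#' acquired at `t0_s + (i - 1) * frame_interval_s` seconds post-injection.
#'
#' @param frames Numeric array `H x W x T` of non-negative intensities.
#' @param frame_interval_s Frame interval, seconds (> 0).
#' @param pixel_size_mm Pixel size, mm/pixel.
#' @param t0_s Recording start relative to injection, seconds (default 0;
#'   positive when recording started late).
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_interval_s, pixel_size_mm, t0_s = 0) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (!is.numeric(frame_interval_s) || frame_interval_s <= 0)
    stop("frame_interval_s must be > 0", call. = FALSE)
  if (!is.numeric(pixel_size_mm) || pixel_size_mm <= 0)
    stop("pixel_size_mm must be > 0", call. = FALSE)
  if (min(frames) < 0)
    stop("frame intensities must be non-negative", call. = FALSE)
  structure(
    list(frames = frames,
         frame_interval_s = as.numeric(frame_interval_s),
         pixel_size_mm = as.numeric(pixel_size_mm),
         t0_s = as.numeric(t0_s)),
    class = "frame_stack"
  )
}

#' Frame timestamps of a stack
#'
#' @param stack A [frame_stack()].
#' @return Numeric vector of frame times, seconds post-injection.
#' @export
stack_times <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  stack$t0_s + (seq_len(dim(stack$frames)[3]) - 1L) * stack$frame_interval_s
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d x %d px, %d frames @ %.3f s (%.1f s), %.3f mm/px, t0 = %.1f s\n",
              d[1], d[2], d[3], x$frame_interval_s,
              d[3] * x$frame_interval_s, x$pixel_size_mm, x$t0_s))
  invisible(x)
}

#' Construct a per-ROI intensity trace
#'
#' The unit of all packet analysis: the mean ROI intensity of each frame,
#' together with background statistics used for SNR and detection
#' thresholds.
#'
#' @param roi_label Label of the source ROI.
#' @param times_s Strictly increasing sample times, seconds post-injection.
#' @param values Mean ROI intensity per frame (same length as `times_s`).
#' @param background_mean,background_sd Background reference statistics
#'   (arbitrary units; `background_sd >= 0`).
#' @return An object of class `intensity_trace`.
#' @export
intensity_trace <- function(roi_label, times_s, values,
                            background_mean = NA_real_,
                            background_sd = NA_real_) {
  times_s <- as.numeric(times_s); values <- as.numeric(values)
  if (length(times_s) != length(values))
    stop("times_s and values must have equal length", call. = FALSE)
  if (length(times_s) > 1 && any(diff(times_s) <= 0))
    stop("times_s must be strictly increasing", call. = FALSE)
  if (!is.na(background_sd) && background_sd < 0)
    stop("background_sd must be >= 0", call. = FALSE)
  structure(
    list(roi_label = as.character(roi_label), times_s = times_s,
         values = values, background_mean = as.numeric(background_mean),
         background_sd = as.numeric(background_sd)),
    class = "intensity_trace"
  )
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("<intensity_trace> '%s': %d samples, t = [%.2f, %.2f] s, bg %.2f +/- %.2f\n",
              x$roi_label, length(x$values),
              if (length(x$times_s)) min(x$times_s) else NA,
              if (length(x$times_s)) max(x$times_s) else NA,
              x$background_mean, x$background_sd))
  invisible(x)
}

#' @export
plot.intensity_trace <- function(x, ...) {
  graphics::plot(x$times_s, x$values, type = "l",
                 xlab = "time post-injection (s)",
                 ylab = "mean ROI intensity (a.u.)",
                 main = x$roi_label, ...)
  if (is.finite(x$background_mean))
    graphics::abline(h = x$background_mean, lty = 3)
  invisible(x)
}

# median inter-sample spacing; traces are normally uniformly sampled
trace_dt <- function(trace) {
  if (length(trace$times_s) < 2) return(NA_real_)
  stats::median(diff(trace$times_s))
}

#' Analysis segment
#'
#' A named time window over which packet metrics are computed. The two
#' standard segments are 100 s long: `arrival` starts 60 s after per-vessel
#' fluorescence arrival; `steady_state` starts 10 min post-injection.
#'
#' @param name Segment name, e.g. `"arrival"` or `"steady_state"`.
#' @param start_s,end_s Window bounds, seconds post-injection
#'   (`end_s > start_s >= 0`).
#' @param truncated,overlaps Bookkeeping flags set by [define_segments()].
#' @return An object of class `segment`.
#' @export
segment <- function(name, start_s, end_s, truncated = FALSE, overlaps = FALSE) {
  start_s <- as.numeric(start_s); end_s <- as.numeric(end_s)
  if (start_s < 0) stop("segment start_s must be >= 0", call. = FALSE)
  if (end_s <= start_s) stop("segment must have end_s > start_s", call. = FALSE)
  structure(list(name = as.character(name), start_s = start_s, end_s = end_s,
                 truncated = isTRUE(truncated), overlaps = isTRUE(overlaps)),
            class = "segment")
}

#' @export
print.segment <- function(x, ...) {
  cat(sprintf("<segment> %s: [%.1f, %.1f] s%s%s\n", x$name, x$start_s, x$end_s,
              if (x$truncated) " [truncated]" else "",
              if (x$overlaps) " [overlaps]" else ""))
  invisible(x)
}

segment_duration_s <- function(seg) seg$end_s - seg$start_s

# logical index of trace samples inside a segment (closed on the left,
# open on the right so adjacent segments do not share samples)
segment_index <- function(trace, seg) {
  trace$times_s >= seg$start_s & trace$times_s < seg$end_s
}
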