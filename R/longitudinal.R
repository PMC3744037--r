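#' Injection-site retention curve
#'
#' Tracks tracer retention across follow-up days: per-day SNR of the
#' injection-site ROI via [snr_db()], with the conventional 3 dB visibility
#' limit. `last_visible_day` is the last sampled day whose SNR exceeds the
#' limit.
#'
#' @param series List of `list(day =, stack =)` entries (>= 2 time points,
#'   day 0 present), e.g. from [simulate_retention_series()].
#' @param injection_roi Injection-site `roi`.
#' @param background_roi Background `roi`.
#' @param limit_db Visibility limit in dB (default 3).
#' @param mode dB convention passed to [snr_db()].
#' @return Data frame of class `retention_curve` with columns `day`,
#'   `snr_db`, `visible`, and attribute `last_visible_day` (`NA` if never
#'   visible).
#' @export
retention_curve <- function(series, injection_roi, background_roi,
                            limit_db = 3, mode = "amplitude") {
  stopifnot(is.list(series), length(series) >= 2)
  days <- vapply(series, `[[`, 0, "day")
  if (!any(days == 0)) stop("no day-0 reference in series", call. = FALSE)
  ord <- order(days)
  rows <- lapply(series[ord], function(e) {
    tr <- extract_trace(e$stack, injection_roi, background_roi)
    s <- snr_db(tr, mode = mode)
    data.frame(day = e$day, snr_db = as.numeric(s),
               visible = is.finite(s) && s > limit_db)
  })
  out <- do.call(rbind, rows)
  vis <- out$day[out$visible]
  attr(out, "last_visible_day") <- if (length(vis)) max(vis) else NA_real_
  class(out) <- c("retention_curve", "data.frame")
  out
}

#' Percent change between a baseline and a follow-up value
#'
#' `100 * (followup - baseline) / baseline`; zero baseline is an error.
#'
#' @param baseline,followup Numeric values (vectorised).
#' @return Percent change.
#' @export
#' @examples
#' percent_change(100, 300)  # +200
percent_change <- function(baseline, followup) {
  if (any(baseline == 0, na.rm = TRUE))
    stop("percent change is undefined for a zero baseline", call. = FALSE)
  100 * (followup - baseline) / baseline
}

#' Projected two-dimensional lymph-node area
#'
#' For a binary mask, the area is the foreground pixel count times the
#' pixel area (exact by construction). For a grayscale image, the node is
#' segmented by Otsu thresholding, keeping the largest connected component
#' and filling holes, then measured the same way.
#'
#' @param image Numeric matrix: grayscale image (scaled to `[0, 1]`
#'   internally) or binary mask (logical, or numeric containing only 0/1).
#' @param pixel_size_mm Pixel size, mm/pixel.
#' @return Area in mm^2.
#' @export
node_area <- function(image, pixel_size_mm) {
  stopifnot(is.matrix(image), pixel_size_mm > 0)
  is_mask <- is.logical(image) || all(image %in% c(0, 1))
  if (is_mask) {
    n_fg <- sum(image != 0)
    if (n_fg == 0) stop("empty foreground", call. = FALSE)
    return(n_fg * pixel_size_mm^2)
  }
  rng <- range(image)
  norm <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  img <- EBImage::Image(norm)
  th <- img > EBImage::otsu(img)
  lab <- EBImage::bwlabel(th)
  sizes <- tabulate(as.integer(lab))
  if (!length(sizes) || max(sizes) == 0)
    stop("empty foreground after thresholding", call. = FALSE)
  keep <- lab == which.max(sizes)
  filled <- EBImage::fillHull(keep)
  sum(EBImage::imageData(filled) != 0) * pixel_size_mm^2
}

#' Compile the longitudinal time-course table
#'
#' Builds the tidy table underlying the week 0/1/2/4 comparisons: one row
#' per animal, week, vessel role, and metric-segment combination, with the
#' week-0 value of the same animal/role/metric joined as baseline and the
#' percent change computed. Transport time is a per-session quantity; it is
#' entered under both segment families so that every analysis family
#' contains the three function metrics. Optional node measurements are
#' appended as metric `node_area`, segment `session`. Missing metrics
#' propagate as `NA` and are excluded (with a count attribute) from
#' downstream paired tests.
#'
#' @param sessions List of `session_result`s (weeks in 0/1/2/4; every
#'   follow-up animal needs a week-0 session).
#' @param nodes Optional data frame with columns `animal_id`, `week`,
#'   `group`, `area_mm2` (> 0).
#' @return Data frame of class `timecourse_table` with columns `animal_id`,
#'   `week`, `group`, `role`, `metric`, `segment`, `value`, `baseline`,
#'   `pct_change`.
#' @export
compile_timecourse <- function(sessions, nodes = NULL) {
  stopifnot(is.list(sessions), length(sessions) >= 1)
  weeks <- vapply(sessions, `[[`, 0, "week")
  if (!all(weeks %in% c(0, 1, 2, 4)))
    stop("weeks must be in {0, 1, 2, 4}", call. = FALSE)
  long <- do.call(rbind, lapply(sessions, function(s) {
    do.call(rbind, lapply(names(s$metrics), function(v) {
      m <- s$metrics[[v]]
      data.frame(
        animal_id = as.character(s$animal_id), week = s$week,
        group = as.character(s$group),
        role = if (v == s$dominant) "dominant" else "non_dominant",
        metric = c("transport_time", "transport_time", "packet_frequency",
                   "packet_frequency", "packet_velocity", "packet_velocity"),
        segment = rep(c("arrival", "steady_state"), 3),
        value = c(m$transport_time_s, m$transport_time_s, m$freq_arrival,
                  m$freq_steady, m$vel_arrival, m$vel_steady),
        stringsAsFactors = FALSE)
    }))
  }))
  if (!is.null(nodes)) {
    stopifnot(all(c("animal_id", "week", "group", "area_mm2") %in%
                    names(nodes)))
    if (any(nodes$area_mm2 <= 0, na.rm = TRUE))
      stop("node areas must be > 0", call. = FALSE)
    long <- rbind(long, data.frame(
      animal_id = as.character(nodes$animal_id), week = nodes$week,
      group = as.character(nodes$group), role = "node",
      metric = "node_area", segment = "session",
      value = nodes$area_mm2, stringsAsFactors = FALSE))
  }
  base <- long[long$week == 0, c("animal_id", "role", "metric", "segment",
                                 "value")]
  names(base)[names(base) == "value"] <- "baseline"
  out <- merge(long, base,
               by = c("animal_id", "role", "metric", "segment"),
               all.x = TRUE, sort = FALSE)
  base_animals <- unique(long$animal_id[long$week == 0])
  fup_animals <- unique(long$animal_id[long$week > 0])
  bad <- setdiff(fup_animals, base_animals)
  if (length(bad))
    stop("follow-up without a week-0 baseline for animal(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  out$pct_change <- ifelse(
    out$week > 0 & !is.na(out$baseline) & out$baseline != 0,
    100 * (out$value - out$baseline) / out$baseline, NA_real_)
  out <- out[order(out$animal_id, out$week, out$role, out$metric,
                   out$segment),
             c("animal_id", "week", "group", "role", "metric", "segment",
               "value", "baseline", "pct_change")]
  rownames(out) <- NULL
  attr(out, "n_missing") <- sum(is.na(out$value))
  class(out) <- c("timecourse_table", "data.frame")
  out
}
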