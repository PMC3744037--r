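#' Write a frame stack as multi-page TIFF with a YAML sidecar
#'
#' Pixel intensities are stored as 16-bit grayscale integer counts
#' (0..65535); the sidecar `<path>.yaml` records `frame_interval_s`,
#' `pixel_size_mm`, and `t0_s`. Round-trips are bit exact for
#' integer-valued stacks (all stacks produced by [simulate_video()] are).
#'
#' @param stack A [frame_stack()] with integer-valued intensities.
#' @param path Output TIFF path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  fr <- stack$frames
  if (max(fr) > 65535)
    stop("intensities exceed the 16-bit range", call. = FALSE)
  if (max(abs(fr - round(fr))) > 1e-9)
    stop("stack intensities must be integer counts for 16-bit storage",
         call. = FALSE)
  pages <- lapply(seq_len(dim(fr)[3]), function(i) fr[, , i] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(frame_interval_s = stack$frame_interval_s,
               pixel_size_mm = stack$pixel_size_mm,
               t0_s = stack$t0_s)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a frame stack written by [write_stack()]
#'
#' Requires the sidecar metadata file; missing calibration is an error,
#' never a silent default.
#'
#' @param path TIFF path (sidecar expected at `<path>.yaml`).
#' @return A [frame_stack()].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sidecar <- paste0(path, ".yaml")
  if (!file.exists(sidecar))
    stop("missing sidecar metadata file: ", sidecar, call. = FALSE)
  meta <- yaml::read_yaml(sidecar)
  for (f in c("frame_interval_s", "pixel_size_mm")) {
    if (is.null(meta[[f]]))
      stop("sidecar is missing required field '", f, "'", call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent page shapes in ", path, call. = FALSE)
  frames <- array(0, c(dims[1, 1], dims[2, 1], length(pages)))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3) p <- p[, , 1]    # tolerate grayscale-as-RGB
    frames[, , i] <- round(p * 65535)
  }
  frame_stack(frames, meta$frame_interval_s, meta$pixel_size_mm,
              t0_s = if (is.null(meta$t0_s)) 0 else meta$t0_s)
}

#' Write an ROI set to JSON
#'
#' @param rois List of [roi_rect()]/[roi_polyline()] objects.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  stopifnot(is.list(rois), all(vapply(rois, inherits, TRUE, "roi")))
  enc <- lapply(rois, function(r) {
    out <- list(label = r$label, purpose = r$purpose, type = r$type,
                axial_origin_mm = r$axial_origin_mm)
    if (r$type == "rect") {
      out$rect <- c(r$x0, r$y0, r$x1, r$y1)
    } else {
      out$points <- r$points
      out$width_px <- r$width_px
    }
    out
  })
  jsonlite::write_json(unname(enc), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read and validate an ROI set from JSON
#'
#' @param path JSON path in the schema written by [write_rois()].
#' @param dim Optional frame dimensions `c(H, W)`; when given, geometry is
#'   checked against the frame bounds and vessel/background overlap.
#' @param check When `TRUE` (default), require a valid function-session set
#'   (>= 2 vessel ROIs, exactly 1 background ROI).
#' @return List of `roi` objects (named by label).
#' @export
read_rois <- function(path, dim = NULL, check = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  rois <- lapply(raw, function(r) {
    if (is.null(r$label) || is.null(r$purpose) || is.null(r$type))
      stop("ROI entry missing label/purpose/type", call. = FALSE)
    origin <- if (is.null(r$axial_origin_mm)) 100 else r$axial_origin_mm
    if (r$type == "rect") {
      roi_rect(r$label, r$purpose, r$rect[1], r$rect[2], r$rect[3], r$rect[4],
               axial_origin_mm = origin)
    } else if (r$type == "polyline") {
      pts <- r$points
      if (is.list(pts)) pts <- do.call(rbind, pts)
      roi_polyline(r$label, r$purpose, pts, r$width_px,
                   axial_origin_mm = origin)
    } else stop("unknown ROI type: ", r$type, call. = FALSE)
  })
  names(rois) <- vapply(rois, `[[`, "", "label")
  if (check) validate_rois(rois, dim = dim)
  if (!is.null(dim)) for (r in rois) invisible(roi_mask(r, dim))
  rois
}

#' Export an intensity trace to CSV
#'
#' Two columns (`time_s`, `value`); the ROI label and background statistics
#' travel in `#`-prefixed header comments so the file round-trips.
#'
#' @param trace An [intensity_trace()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "intensity_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# roi_label: ", trace$roi_label),
               paste0("# background_mean: ",
                      format(trace$background_mean, digits = 17)),
               paste0("# background_sd: ",
                      format(trace$background_sd, digits = 17))), con)
  utils::write.csv(data.frame(time_s = trace$times_s,
                              value = trace$values),
                   con, row.names = FALSE)
  invisible(path)
}

#' Read a trace CSV written by [write_trace()]
#'
#' @param path CSV path.
#' @return An [intensity_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "# ")]
  get <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (!length(ln)) return(NA)
    sub(paste0("^# ", key, ": "), "", ln[1])
  }
  df <- utils::read.csv(path, comment.char = "#")
  intensity_trace(get("roi_label"), df$time_s, df$value,
                  background_mean = as.numeric(get("background_mean")),
                  background_sd = as.numeric(get("background_sd")))
}

# stable column schema of the per-vessel results table
results_columns <- c("animal_id", "week", "group", "vessel", "role",
                     "dominance_source", "transport_time_s",
                     "freq_arrival_per_min", "freq_steady_per_min",
                     "vel_arrival_mm_s", "vel_steady_mm_s")

#' Write session results to a flat CSV
#'
#' One row per vessel per session, stable documented columns
#' (`animal_id, week, group, vessel, role, dominance_source,
#' transport_time_s, freq_arrival_per_min, freq_steady_per_min,
#' vel_arrival_mm_s, vel_steady_mm_s`). Missing metrics are written as
#' empty cells (`NA`), never zeros.
#'
#' @param session_results A single `session_result` or a list of them (an
#'   empty list yields a header-only file).
#' @param path Output CSV path.
#' @param comment Optional comment lines (written with a leading `#`).
#' @return The written data frame, invisibly.
#' @export
write_results <- function(session_results, path, comment = NULL) {
  df <- sessions_to_df(session_results)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(df)
}

#' Read a results CSV written by [write_results()]
#'
#' @param path CSV path.
#' @return Data frame with the documented columns.
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c(animal_id = "character",
                                       group = "character",
                                       vessel = "character",
                                       role = "character",
                                       dominance_source = "character"))
  missing <- setdiff(results_columns, names(df))
  if (length(missing))
    stop("results file is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

sessions_to_df <- function(session_results) {
  if (inherits(session_results, "session_result"))
    session_results <- list(session_results)
  stopifnot(is.list(session_results))
  empty <- as.data.frame(stats::setNames(
    rep(list(character(0)), length(results_columns)), results_columns))
  if (!length(session_results)) return(empty)
  rows <- lapply(session_results, function(s) {
    stopifnot(inherits(s, "session_result"))
    do.call(rbind, lapply(names(s$metrics), function(v) {
      m <- s$metrics[[v]]
      data.frame(animal_id = as.character(s$animal_id), week = s$week,
                 group = as.character(s$group), vessel = v,
                 role = if (v == s$dominant) "dominant" else "non_dominant",
                 dominance_source = s$dominance_source,
                 transport_time_s = m$transport_time_s,
                 freq_arrival_per_min = m$freq_arrival,
                 freq_steady_per_min = m$freq_steady,
                 vel_arrival_mm_s = m$vel_arrival,
                 vel_steady_mm_s = m$vel_steady,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
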