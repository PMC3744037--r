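#' Rectangular region of interest
#'
#' Pixel coordinates are 0-based and half-open: a rectangle covers columns
#' `x0 <= x < x1` and rows `y0 <= y < y1`. Vessel ROIs have a well-defined
#' axial direction running with increasing `x` (injection-proximal at `x0`,
#' distal at `x1`), and carry the axial distance of the ROI start from the
#' injection site (default 100 mm, the standard imaging-window offset).
#'
#' @param label ROI label.
#' @param purpose One of `"vessel"`, `"background"`, `"injection_site"`,
#'   `"node"`.
#' @param x0,y0,x1,y1 Rectangle bounds (0-based, half-open).
#' @param axial_origin_mm Distance of the ROI start from the injection site
#'   in mm (vessel ROIs).
#' @return An object of class `roi`.
#' @export
roi_rect <- function(label, purpose, x0, y0, x1, y1, axial_origin_mm = 100) {
  purpose <- match.arg(purpose,
                       c("vessel", "background", "injection_site", "node"))
  if (x1 <= x0 || y1 <= y0)
    stop("ROI rectangle must have x1 > x0 and y1 > y0", call. = FALSE)
  if (x0 < 0 || y0 < 0)
    stop("ROI coordinates must be >= 0", call. = FALSE)
  structure(
    list(label = as.character(label), purpose = purpose, type = "rect",
         x0 = as.integer(x0), y0 = as.integer(y0),
         x1 = as.integer(x1), y1 = as.integer(y1),
         axial_origin_mm = as.numeric(axial_origin_mm)),
    class = "roi"
  )
}

#' Polyline (centreline) region of interest
#'
#' A vessel ROI given as a centreline polyline with a width; the mask is the
#' set of pixels whose centre lies within `width_px / 2` of the polyline.
#' The axial direction runs along the polyline from its first point.
#'
#' @param label,purpose,axial_origin_mm As in [roi_rect()].
#' @param points Numeric matrix `n x 2` of 0-based `(x, y)` vertices,
#'   `n >= 2`.
#' @param width_px Full width in pixels.
#' @return An object of class `roi`.
#' @export
roi_polyline <- function(label, purpose, points, width_px,
                         axial_origin_mm = 100) {
  purpose <- match.arg(purpose,
                       c("vessel", "background", "injection_site", "node"))
  points <- as.matrix(points)
  if (ncol(points) != 2 || nrow(points) < 2)
    stop("polyline needs an n x 2 matrix with n >= 2", call. = FALSE)
  if (width_px <= 0) stop("width_px must be > 0", call. = FALSE)
  structure(
    list(label = as.character(label), purpose = purpose, type = "polyline",
         points = unname(points), width_px = as.numeric(width_px),
         axial_origin_mm = as.numeric(axial_origin_mm)),
    class = "roi"
  )
}

#' @export
print.roi <- function(x, ...) {
  if (x$type == "rect") {
    cat(sprintf("<roi> '%s' (%s): rect [%d,%d) x [%d,%d)\n", x$label,
                x$purpose, x$x0, x$x1, x$y0, x$y1))
  } else {
    cat(sprintf("<roi> '%s' (%s): polyline, %d vertices, width %.1f px, length %.2f px\n",
                x$label, x$purpose, nrow(x$points), x$width_px,
                polyline_length_px(x$points)))
  }
  invisible(x)
}

polyline_length_px <- function(points) {
  sum(sqrt(rowSums(diff(points)^2)))
}

#' Axial length of a vessel ROI in mm
#'
#' Rectangles: `(x1 - x0) * pixel_size_mm`. Polylines: arc length of the
#' centreline times the pixel size.
#'
#' @param roi An [roi_rect()] or [roi_polyline()].
#' @param pixel_size_mm Pixel size, mm/pixel.
#' @return Length in mm.
#' @export
roi_axial_length_mm <- function(roi, pixel_size_mm) {
  stopifnot(inherits(roi, "roi"))
  if (roi$type == "rect") (roi$x1 - roi$x0) * pixel_size_mm
  else polyline_length_px(roi$points) * pixel_size_mm
}

#' Pixel mask of an ROI
#'
#' @param roi An `roi`.
#' @param dim Frame dimensions `c(H, W)`.
#' @return Logical `H x W` matrix.
#' @export
roi_mask <- function(roi, dim) {
  stopifnot(inherits(roi, "roi"), length(dim) >= 2)
  H <- dim[1]; W <- dim[2]
  m <- matrix(FALSE, H, W)
  if (roi$type == "rect") {
    if (roi$x1 > W || roi$y1 > H)
      stop("ROI '", roi$label, "' exceeds frame bounds", call. = FALSE)
    m[(roi$y0 + 1):roi$y1, (roi$x0 + 1):roi$x1] <- TRUE
  } else {
    pts <- roi$points
    if (any(pts[, 1] < 0 | pts[, 1] > W - 1 | pts[, 2] < 0 | pts[, 2] > H - 1))
      stop("ROI '", roi$label, "' exceeds frame bounds", call. = FALSE)
    half <- roi$width_px / 2
    # pixel centres at 0-based integer coordinates
    xs <- matrix(rep(0:(W - 1), each = H), H, W)
    ys <- matrix(rep(0:(H - 1), times = W), H, W)
    d2 <- matrix(Inf, H, W)
    for (i in seq_len(nrow(pts) - 1)) {
      a <- pts[i, ]; b <- pts[i + 1, ]
      ab <- b - a
      len2 <- sum(ab^2)
      t <- if (len2 == 0) 0 else
        pmin(1, pmax(0, ((xs - a[1]) * ab[1] + (ys - a[2]) * ab[2]) / len2))
      d2 <- pmin(d2, (xs - (a[1] + t * ab[1]))^2 + (ys - (a[2] + t * ab[2]))^2)
    }
    m <- d2 <= half^2
  }
  if (!any(m)) stop("ROI '", roi$label, "' has an empty mask", call. = FALSE)
  m
}

#' Validate an ROI set for a function-imaging session
#'
#' A function session needs at least two vessel ROIs and exactly one
#' background ROI; vessel and background masks must not overlap and all
#' geometry must lie within the frame.
#'
#' @param rois List of `roi` objects.
#' @param dim Optional frame dimensions `c(H, W)` for bounds/overlap checks.
#' @return The ROI list, invisibly; errors on violation.
#' @export
validate_rois <- function(rois, dim = NULL) {
  stopifnot(is.list(rois), all(vapply(rois, inherits, TRUE, "roi")))
  purposes <- vapply(rois, `[[`, "", "purpose")
  if (sum(purposes == "vessel") < 2)
    stop("need at least two vessel ROIs", call. = FALSE)
  if (sum(purposes == "background") != 1)
    stop("need exactly one background ROI", call. = FALSE)
  if (!is.null(dim)) {
    masks <- lapply(rois, roi_mask, dim = dim)
    bg <- masks[[which(purposes == "background")]]
    for (i in which(purposes == "vessel")) {
      if (any(masks[[i]] & bg))
        stop("background ROI overlaps vessel ROI '", rois[[i]]$label, "'",
             call. = FALSE)
    }
    vi <- which(purposes == "vessel")
    for (i in vi) for (j in vi) if (i < j) {
      if (any(masks[[i]] & masks[[j]]))
        stop("vessel ROIs '", rois[[i]]$label, "' and '", rois[[j]]$label,
             "' overlap", call. = FALSE)
    }
  }
  invisible(rois)
}

#' Subdivide a vessel ROI into axial sub-ROIs
#'
#' Splits a vessel ROI into `n` contiguous, equal-axial-length sub-ROIs
#' ordered from injection-proximal to distal. Each sub-ROI carries an
#' `axial_mid_mm` attribute: the axial midpoint in mm measured from the
#' injection site (`axial_origin_mm` + offset within the ROI). The sub-ROI
#' masks partition the parent mask.
#'
#' @param roi A vessel `roi`.
#' @param n Number of sub-ROIs (>= 2).
#' @param pixel_size_mm Pixel size, mm/pixel.
#' @return List of `n` `roi` objects with `axial_mid_mm` attributes.
#' @export
subdivide_vessel_roi <- function(roi, n, pixel_size_mm) {
  stopifnot(inherits(roi, "roi"))
  if (roi$purpose != "vessel")
    stop("only vessel ROIs can be subdivided", call. = FALSE)
  n <- as.integer(n)
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (roi$type == "rect") {
    len <- roi$x1 - roi$x0
    if (n > len) stop("n exceeds ROI axial pixel count", call. = FALSE)
    breaks <- roi$x0 + round(seq(0, len, length.out = n + 1))
    lapply(seq_len(n), function(i) {
      sub <- roi_rect(paste0(roi$label, "_", i), "vessel",
                      breaks[i], roi$y0, breaks[i + 1], roi$y1,
                      axial_origin_mm = roi$axial_origin_mm)
      attr(sub, "axial_mid_mm") <- roi$axial_origin_mm +
        ((breaks[i] + breaks[i + 1]) / 2 - roi$x0) * pixel_size_mm
      sub
    })
  } else {
    # split the centreline at equal arc-length fractions
    pts <- roi$points
    seglen <- sqrt(rowSums(diff(pts)^2))
    cum <- c(0, cumsum(seglen))
    total <- cum[length(cum)]
    if (n > floor(total)) stop("n exceeds ROI axial pixel count", call. = FALSE)
    point_at <- function(s) {
      i <- max(which(cum <= s + 1e-9)); i <- min(i, nrow(pts) - 1)
      f <- if (seglen[i] == 0) 0 else (s - cum[i]) / seglen[i]
      pts[i, ] + f * (pts[i + 1, ] - pts[i, ])
    }
    lapply(seq_len(n), function(i) {
      s0 <- total * (i - 1) / n; s1 <- total * i / n
      # vertices inside (s0, s1) plus interpolated endpoints
      inner <- which(cum > s0 & cum < s1)
      sub_pts <- rbind(point_at(s0), pts[inner, , drop = FALSE], point_at(s1))
      sub <- roi_polyline(paste0(roi$label, "_", i), "vessel", sub_pts,
                          roi$width_px, axial_origin_mm = roi$axial_origin_mm)
      attr(sub, "axial_mid_mm") <- roi$axial_origin_mm +
        (s0 + s1) / 2 * pixel_size_mm
      sub
    })
  }
}

#' Default ROI set matching the simulator's video geometry
#'
#' Two vessel rectangles centred on the simulated vessel stripes, plus one
#' background rectangle in the top margin of the frame.
#'
#' @param config A [sim_config()].
#' @return List of three `roi` objects named `v1`, `v2`, `background`.
#' @export
default_rois <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  hw <- config$roi_row_halfwidth_px
  len_px <- round(config$roi_length_mm / config$pixel_size_mm)
  x0 <- config$roi_x0_px
  vroi <- function(i) {
    r <- config$vessel_row_px[i]
    roi_rect(paste0("v", i), "vessel", x0, r - hw, x0 + len_px, r + hw + 1,
             axial_origin_mm = config$axial_origin_mm)
  }
  list(v1 = vroi(1), v2 = vroi(2),
       background = roi_rect("background", "background",
                             0, 0, config$frame_width_px, 3))
}
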