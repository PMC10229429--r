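#' Segment the animal body in a thermal frame
#'
#' Thresholds the frame at `ambient + t_threshold` and keeps the largest
#' 4-connected component. The ambient temperature, if not supplied, is
#' estimated as the mode of the frame border pixels (binned to 0.1 degC).
#' An empty mask (no pixel above threshold) is a valid result.
#'
#' @param frame numeric temperature matrix, degC
#' @param t_threshold_above_ambient segmentation margin above ambient, degC
#' @param ambient_estimate ambient temperature, degC; estimated from the
#'   border when `NULL`
#' @return logical matrix, TRUE on the body
#' @export
segment_body <- function(frame, t_threshold_above_ambient = 4,
                         ambient_estimate = NULL) {
  if (anyNA(frame) || any(!is.finite(frame))) {
    stop("`frame` must be finite", call. = FALSE)
  }
  if (is.null(ambient_estimate)) {
    border <- c(frame[1, ], frame[nrow(frame), ],
                frame[, 1], frame[, ncol(frame)])
    bins <- round(border, 1)
    ambient_estimate <- as.numeric(names(which.max(table(bins))))
  }
  warm <- frame > ambient_estimate + t_threshold_above_ambient
  if (!any(warm)) return(matrix(FALSE, nrow(frame), ncol(frame)))
  lab <- EBImage::bwlabel(warm * 1)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

#' Estimate body pose from a segmentation mask
#'
#' Centroid from the mask pixel coordinates, body axis from the principal
#' eigenvector of the coordinate second moments, body length from the extent
#' of the mask projected on that axis. Before the moments are taken the mask
#' is cleaned by a morphological opening (`open_px` box) that removes
#' structures thinner than the kernel -- in particular the tail, which would
#' otherwise drag the centroid posterior and inflate the body length.
#'
#' The principal axis leaves the anterior direction ambiguous; it is
#' resolved by `head_hint`: either an explicit (row, col) coordinate the
#' head is nearest to, or `"warmer"` (default, requires `frame`), which
#' orients toward the body half with the hotter upper-decile temperature --
#' in rodent thermograms the head carries the hottest surface (eyes), and
#' comparing upper deciles rather than half means keeps the choice stable
#' when the interscapular hotspot on the anterior half cools during a bout.
#'
#' @param mask logical matrix from [segment_body()]
#' @param pixel_size_mm pixel pitch, mm
#' @param frame the temperature frame (needed for the `"warmer"` heuristic)
#' @param head_hint `"warmer"` or a numeric c(row, col)
#' @param min_pixels masks smaller than this are rejected as degenerate
#' @param open_px box kernel width (px) of the tail-removing opening; use
#'   1 to disable
#' @return object of class `body_pose`: list with `centroid_px`,
#'   `anterior_unit` (row, col, unit norm), `body_length_mm`, `mask` (the
#'   cleaned mask actually used), `pixel_size_mm`
#' @export
estimate_pose <- function(mask, pixel_size_mm, frame = NULL,
                          head_hint = "warmer", min_pixels = 10,
                          open_px = 3) {
  if (!any(mask)) stop("no body detected", call. = FALSE)
  if (open_px > 1) {
    opened <- EBImage::opening(mask * 1,
                               EBImage::makeBrush(open_px, "box")) > 0
    if (sum(opened) >= min_pixels) mask <- opened
  }
  px <- which(mask, arr.ind = TRUE)
  if (nrow(px) < min_pixels) {
    stop(sprintf("degenerate mask: %d px < %d", nrow(px), min_pixels),
         call. = FALSE)
  }
  centroid <- colMeans(px)
  cov2 <- stats::cov(px)
  eig <- eigen(cov2, symmetric = TRUE)
  u <- eig$vectors[, 1]
  u <- u / sqrt(sum(u^2))
  along <- (px[, 1] - centroid[1]) * u[1] + (px[, 2] - centroid[2]) * u[2]
  body_length_px <- max(along) - min(along) + 1

  if (is.numeric(head_hint) && length(head_hint) == 2) {
    toward <- (head_hint[1] - centroid[1]) * u[1] +
      (head_hint[2] - centroid[2]) * u[2]
    if (toward < 0) u <- -u
  } else if (identical(head_hint, "warmer")) {
    if (is.null(frame)) {
      stop("`frame` is required for head_hint = \"warmer\"", call. = FALSE)
    }
    vals <- frame[mask]
    upper_decile_mean <- function(v) {
      if (length(v) == 0) return(-Inf)
      mean(v[v >= stats::quantile(v, 0.9)])
    }
    if (upper_decile_mean(vals[along > 0]) <
        upper_decile_mean(vals[along < 0])) u <- -u
  } else {
    stop("`head_hint` must be \"warmer\" or a c(row, col) coordinate",
         call. = FALSE)
  }

  structure(list(
    centroid_px = unname(centroid),
    anterior_unit = u,
    body_length_mm = body_length_px * pixel_size_mm,
    mask = mask,
    pixel_size_mm = pixel_size_mm
  ), class = "body_pose")
}

#' Disk region of interest
#'
#' @param center_px ROI center, c(row, col) px
#' @param radius_mm ROI radius, mm (> 0)
#' @param clipped whether the center fell outside the frame when located
#' @return object of class `disk_roi`
#' @export
disk_roi <- function(center_px, radius_mm, clipped = FALSE) {
  assert_number(radius_mm, "radius_mm", 0, strict_lower = TRUE)
  structure(list(center_px = as.numeric(center_px), radius_mm = radius_mm,
                 clipped = isTRUE(clipped)),
            class = "disk_roi")
}

#' Locate the BAT region of interest from a body pose
#'
#' Places a disk of `radius_mm` at `fraction` of the body length anterior to
#' the body centroid, the interscapular BAT site. If the center falls outside
#' the frame, the ROI is flagged `clipped` and [roi_mean()] averages over the
#' in-frame intersection.
#'
#' @param pose a [estimate_pose()] result
#' @param fraction offset anterior of the centroid as a fraction of body
#'   length (default 0.25)
#' @param radius_mm ROI radius, mm (default 3)
#' @return a [disk_roi()]
#' @export
locate_bat_roi <- function(pose, fraction = 0.25, radius_mm = 3) {
  stopifnot(inherits(pose, "body_pose"))
  offset_px <- fraction * pose$body_length_mm / pose$pixel_size_mm
  ctr <- pose$centroid_px + offset_px * pose$anterior_unit
  d <- dim(pose$mask)
  clipped <- ctr[1] < 1 || ctr[1] > d[1] || ctr[2] < 1 || ctr[2] > d[2]
  disk_roi(ctr, radius_mm, clipped = clipped)
}

#' Mean temperature within a disk ROI
#'
#' Averages the pixels whose centers lie within `radius_mm` of the ROI
#' center (inclusive). Errors if no pixel qualifies.
#'
#' @param frame temperature matrix, degC
#' @param roi a [disk_roi()]
#' @param pixel_size_mm pixel pitch, mm
#' @return mean temperature, degC
#' @export
roi_mean <- function(frame, roi, pixel_size_mm) {
  stopifnot(inherits(roi, "disk_roi"))
  r_px <- roi$radius_mm / pixel_size_mm
  nr <- nrow(frame); nc <- ncol(frame)
  r0 <- roi$center_px[1]; c0 <- roi$center_px[2]
  row_lo <- max(1, floor(r0 - r_px)); row_hi <- min(nr, ceiling(r0 + r_px))
  col_lo <- max(1, floor(c0 - r_px)); col_hi <- min(nc, ceiling(c0 + r_px))
  if (row_lo > row_hi || col_lo > col_hi) {
    stop("ROI outside frame", call. = FALSE)
  }
  rows <- row_lo:row_hi
  cols <- col_lo:col_hi
  sub <- frame[rows, cols, drop = FALSE]
  dr <- matrix(rows - r0, length(rows), length(cols))
  dc <- matrix(cols - c0, length(rows), length(cols), byrow = TRUE)
  sel <- dr^2 + dc^2 <= r_px^2
  if (!any(sel)) stop("ROI outside frame", call. = FALSE)
  mean(sub[sel])
}

#' Mean temperature of the proximal-tail ROI
#'
#' A disk of `diameter_mm` centered `offset_mm` from the tail base along the
#' tail direction -- the proximal-tail site used to monitor heat-dissipating
#' vasodilation. The tail base is supplied by the caller (it was selected
#' manually in the source workflow).
#'
#' @param frame temperature matrix, degC
#' @param tail_base_px tail base, c(row, col) px
#' @param tail_dir unit direction from body toward tail tip (row, col)
#' @param offset_mm distance from base to ROI center, mm (default 10)
#' @param diameter_mm ROI diameter, mm (default 2)
#' @param pixel_size_mm pixel pitch, mm
#' @return mean temperature, degC
#' @export
tail_roi_mean <- function(frame, tail_base_px, tail_dir, offset_mm = 10,
                          diameter_mm = 2, pixel_size_mm = 1) {
  dir <- tail_dir / sqrt(sum(tail_dir^2))
  ctr <- tail_base_px + (offset_mm / pixel_size_mm) * dir
  roi_mean(frame, disk_roi(ctr, diameter_mm / 2), pixel_size_mm)
}

#' Extract a temperature trace from a thermal stack
#'
#' Applies a per-frame ROI source and returns one value per frame with the
#' frame timestamps. The source may be a fixed [disk_roi()], or a function
#' `(frame, index) -> disk_roi` (return `NULL` to mark the frame invalid).
#' Frames whose ROI is invalid or fails yield `NA`.
#'
#' @param stack a [thermal_stack()]
#' @param roi_source a `disk_roi` or a function of (frame, index)
#' @return a [new_trace()] in degC
#' @export
extract_trace <- function(stack, roi_source) {
  stopifnot(inherits(stack, "thermal_stack"))
  if (length(stack$frames) == 0) stop("empty stack", call. = FALSE)
  vals <- vapply(seq_along(stack$frames), function(i) {
    roi <- if (inherits(roi_source, "disk_roi")) roi_source
           else roi_source(stack$frames[[i]], i)
    if (is.null(roi)) return(NA_real_)
    tryCatch(roi_mean(stack$frames[[i]], roi, stack$pixel_size_mm),
             error = function(e) NA_real_)
  }, numeric(1))
  new_trace(stack$time_s, vals, "degC")
}

#' Automated BAT temperature trace from thermal video
#'
#' The full tracking chain per frame: segment the body, estimate the pose,
#' place the BAT ROI at 25% of body length anterior to the centroid and
#' average it. Returns the T_BAT trace; frames where segmentation or pose
#' fails yield `NA`.
#'
#' @param stack a [thermal_stack()]
#' @param t_threshold_above_ambient,ambient_estimate passed to [segment_body()]
#' @param fraction,radius_mm passed to [locate_bat_roi()]
#' @param head_hint passed to [estimate_pose()]
#' @return a [new_trace()] in degC
#' @export
#' @examples
#' tr <- new_trace(seq(0, 30, 5), rep(35, 7), "degC")
#' vid <- render_thermal_video(tr, noise_sd = 0, seed = 1)
#' extract_bat_trace(vid$stack)
extract_bat_trace <- function(stack, t_threshold_above_ambient = 4,
                              ambient_estimate = NULL, fraction = 0.25,
                              radius_mm = 3, head_hint = "warmer") {
  extract_trace(stack, function(frame, i) {
    mask <- segment_body(frame, t_threshold_above_ambient, ambient_estimate)
    if (!any(mask)) return(NULL)
    pose <- tryCatch(
      estimate_pose(mask, stack$pixel_size_mm, frame, head_hint),
      error = function(e) NULL)
    if (is.null(pose)) return(NULL)
    locate_bat_roi(pose, fraction, radius_mm)
  })
}

#' Low-pass filter a uniformly sampled trace
#'
#' Zero-phase Butterworth low-pass (4th order by default) to remove
#' high-frequency camera fluctuation before endpoint extraction. The filter
#' is applied forward and backward over an odd-reflection-padded record with
#' steady-state initial conditions, and the finite-record mean is preserved
#' exactly (unit DC gain).
#'
#' @param trace a trace (data frame with `time_s`, `value`), uniform sampling
#' @param cutoff_hz cutoff frequency, Hz; must be below Nyquist
#' @param order filter order
#' @return filtered trace, same length and times
#' @export
lowpass <- function(trace, cutoff_hz = 0.1, order = 4) {
  out <- butter_zero_phase(trace, cutoff_hz, order, "low")
  out$value <- out$value + mean(as_trace(trace)$value) - mean(out$value)
  out
}
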