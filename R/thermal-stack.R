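#' Thermal video stack
#'
#' Container for temperature-calibrated thermal video: a list of equally
#' shaped matrices in degC, one per frame, with per-frame times in seconds and
#' the pixel pitch in mm. Pixel (r, c) maps to physical coordinates
#' ((r - 1) * pixel_size_mm, (c - 1) * pixel_size_mm), i.e. the first pixel
#' center is the origin.
#'
#' @param frames list of numeric matrices, all the same dimension (degC)
#' @param time_s numeric vector of frame times, strictly increasing
#' @param pixel_size_mm pixel pitch, mm (> 0)
#' @return an object of class `thermal_stack`
#' @export
thermal_stack <- function(frames, time_s, pixel_size_mm) {
  if (!is.list(frames) || length(frames) == 0) {
    stop("`frames` must be a non-empty list of matrices", call. = FALSE)
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must share one shape", call. = FALSE)
  }
  if (length(time_s) != length(frames)) {
    stop("`time_s` must have one entry per frame", call. = FALSE)
  }
  if (length(time_s) > 1 && any(diff(time_s) <= 0)) {
    stop("`time_s` must be strictly increasing", call. = FALSE)
  }
  assert_number(pixel_size_mm, "pixel_size_mm", 0, strict_lower = TRUE)
  structure(list(frames = frames, time_s = as.numeric(time_s),
                 pixel_size_mm = pixel_size_mm),
            class = "thermal_stack")
}

#' @export
#' @method print thermal_stack
print.thermal_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<thermal_stack> %d frames of %d x %d px (%.3g mm/px), %.1f s\n",
              length(x$frames), d[1], d[2], x$pixel_size_mm,
              diff(range(x$time_s))))
  invisible(x)
}

#' @export
length.thermal_stack <- function(x) length(x$frames)

#' Render one frame of a stack
#' @param object a `thermal_stack`
#' @param frame frame index
#' @param ... unused
#' @return a ggplot raster of the frame in degC
#' @export
autoplot.thermal_stack <- function(object, frame = 1L, ...) {
  f <- object$frames[[frame]]
  df <- tidyr::expand_grid(row = seq_len(nrow(f)), col = seq_len(ncol(f)))
  df$temp <- f[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$temp)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "degC") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "col (px)", y = "row (px)",
                  title = sprintf("frame %d, t = %.1f s", frame,
                                  object$time_s[frame]))
}
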