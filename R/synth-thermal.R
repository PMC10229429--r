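#' Render a synthetic thermal video of a mouse with a BAT hotspot
#'
#' Paints, per frame: a uniform background at `t_amb`, an elliptical body at
#' `t_body`, a thin tail segment at `t_tail`, a warm head spot at the anterior
#' tip (so the warmer-end head heuristic used by pose estimation holds), and a
#' circular BAT hotspot whose temperature follows the supplied `t_bat` trace.
#' The hotspot is painted last with the same pixel-center-within-radius rule
#' used by [roi_mean()], so with zero noise the mean over the true ROI equals
#' the programmed trace exactly. Gaussian pixel noise is added on top.
#'
#' Orientation convention: `orientation_deg` is the angle of the anterior
#' (head) direction, measured counterclockwise from the +col image axis;
#' the anterior unit vector in (row, col) pixels is
#' (-sin(theta), cos(theta)).
#'
#' @param t_bat BAT hotspot temperature trace: a data frame with `time_s` and
#'   `value` (degC); frames are rendered at exactly these times
#' @param t_body body surface temperature, degC (scalar or per frame)
#' @param t_tail tail temperature, degC (scalar or per frame)
#' @param t_amb background/ambient temperature, degC
#' @param frame_shape c(rows, cols) in px
#' @param pixel_size_mm pixel pitch, mm
#' @param body_center_px ellipse center as c(row, col), or an n x 2 matrix for
#'   a moving body; default frame center
#' @param semi_axes_mm ellipse semi-axes c(along-body, across-body), mm
#' @param orientation_deg anterior direction, degrees (see Details)
#' @param bat_fraction BAT center offset anterior of the centroid as a
#'   fraction of body length (body length = 2 * semi-major axis)
#' @param bat_radius_mm hotspot radius, mm; the default (5) is larger than
#'   the 3-mm analysis ROI so that small tracking errors stay inside the
#'   uniform patch, as with a physical BAT depot
#' @param head_warm_degC head-spot excess over `t_body`, degC
#' @param tail_length_mm,tail_width_mm tail geometry, mm
#' @param noise_sd pixel noise SD, degC
#' @param seed integer seed
#' @return list with elements `stack` (a [thermal_stack()]) and `truth`, a
#'   list carrying `bat_center_mm` (tibble: frame, time_s, row_mm, col_mm),
#'   `bat_center_px`, `centroid_px`, `anterior_unit`, `body_length_mm` and the
#'   programmed `t_bat` trace
#' @export
#' @examples
#' tr <- new_trace(seq(0, 60, by = 5), rep(35, 13), "degC")
#' vid <- render_thermal_video(tr, noise_sd = 0, seed = 1)
#' vid$stack
render_thermal_video <- function(t_bat,
                                 t_body = 34,
                                 t_tail = 28,
                                 t_amb = 22,
                                 frame_shape = c(60, 80),
                                 pixel_size_mm = 1,
                                 body_center_px = NULL,
                                 semi_axes_mm = c(20, 7),
                                 orientation_deg = 0,
                                 bat_fraction = 0.25,
                                 bat_radius_mm = 5,
                                 head_warm_degC = 1.5,
                                 tail_length_mm = 25,
                                 tail_width_mm = 2,
                                 noise_sd = 0.1,
                                 seed = 1L) {
  t_bat <- as_trace(t_bat, "degC")
  n <- nrow(t_bat)
  assert_number(pixel_size_mm, "pixel_size_mm", 0, strict_lower = TRUE)
  nr <- frame_shape[1]; nc <- frame_shape[2]

  if (is.null(body_center_px)) body_center_px <- c(nr, nc) / 2
  centers <- if (is.matrix(body_center_px)) {
    if (nrow(body_center_px) != n) {
      stop("`body_center_px` matrix must have one row per frame", call. = FALSE)
    }
    body_center_px
  } else {
    matrix(rep(body_center_px, each = n), ncol = 2)
  }

  a_px <- semi_axes_mm[1] / pixel_size_mm
  b_px <- semi_axes_mm[2] / pixel_size_mm
  th <- orientation_deg * pi / 180
  u <- c(-sin(th), cos(th))                 # anterior unit (row, col)
  v <- c(cos(th), sin(th))                  # across-body unit

  if (any(centers[, 1] - a_px < 1) || any(centers[, 1] + a_px > nr) ||
      any(centers[, 2] - a_px < 1) || any(centers[, 2] + a_px > nc)) {
    stop("body does not fit inside the frame", call. = FALSE)
  }

  t_body <- rep_len(t_body, n)
  t_tail <- rep_len(t_tail, n)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  r_bat_px <- bat_radius_mm / pixel_size_mm
  body_len_px <- 2 * a_px

  set.seed(derive_seed(seed))
  frames <- vector("list", n)
  bat_centers <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    ctr <- centers[i, ]
    dr <- rr - ctr[1]; dc <- cc - ctr[2]
    along <- dr * u[1] + dc * u[2]
    across <- dr * v[1] + dc * v[2]
    frame <- matrix(t_amb, nr, nc)
    body <- (along / a_px)^2 + (across / b_px)^2 <= 1
    frame[body] <- t_body[i]
    # tail: thin strip extending from the posterior tip
    tail_sel <- along <= -a_px + 1e-9 & along >= -a_px - tail_length_mm / pixel_size_mm &
      abs(across) <= (tail_width_mm / 2) / pixel_size_mm
    frame[tail_sel] <- t_tail[i]
    # head spot at the anterior tip keeps the anterior half warmer
    head_ctr <- ctr + 0.8 * a_px * u
    head_sel <- (rr - head_ctr[1])^2 + (cc - head_ctr[2])^2 <=
      (3 / pixel_size_mm)^2
    frame[head_sel & body] <- t_body[i] + head_warm_degC
    # BAT hotspot painted last so its pixel set is exactly the ROI pixel set
    bat_ctr <- ctr + bat_fraction * body_len_px * u
    bat_sel <- (rr - bat_ctr[1])^2 + (cc - bat_ctr[2])^2 <= r_bat_px^2
    frame[bat_sel] <- t_bat$value[i]
    if (noise_sd > 0) frame <- frame + rnorm(nr * nc, 0, noise_sd)
    frames[[i]] <- frame
    bat_centers[i, ] <- bat_ctr
  }

  stack <- thermal_stack(frames, t_bat$time_s, pixel_size_mm)
  truth <- list(
    bat_center_px = bat_centers,
    bat_center_mm = tibble::tibble(
      frame = seq_len(n), time_s = t_bat$time_s,
      row_mm = (bat_centers[, 1] - 1) * pixel_size_mm,
      col_mm = (bat_centers[, 2] - 1) * pixel_size_mm
    ),
    centroid_px = centers,
    anterior_unit = u,
    body_length_mm = 2 * semi_axes_mm[1],
    t_bat = t_bat,
    seed = seed
  )
  list(stack = stack, truth = truth)
}
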