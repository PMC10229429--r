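#' Background statistics for positivity thresholds
#'
#' Mean and sample SD of the background pixels: those inside the brain mask
#' but outside every estimated cell area. The positivity criterion downstream
#' is strict exceedance of mean + 3 SD.
#'
#' @param image numeric intensity matrix, a.u.
#' @param brain_mask logical matrix, TRUE inside the tissue
#' @param cell_mask logical matrix, TRUE on cell areas (excluded); `NULL`
#'   excludes nothing
#' @return list of class `background_stats`: `mean`, `sd`, `n_pixels`
#' @export
background_stats <- function(image, brain_mask, cell_mask = NULL) {
  if (is.null(cell_mask)) cell_mask <- array(FALSE, dim(image))
  sel <- brain_mask & !cell_mask
  if (!any(sel)) stop("empty background: brain mask minus cell mask is empty",
                      call. = FALSE)
  vals <- image[sel]
  structure(list(mean = mean(vals),
                 sd = if (length(vals) > 1) sd(vals) else 0,
                 n_pixels = length(vals)),
            class = "background_stats")
}

#' @rdname background_stats
#' @param mean,sd,n_pixels components, for constructing directly
#' @export
new_background_stats <- function(mean, sd, n_pixels = NA_integer_) {
  assert_number(sd, "sd", 0)
  structure(list(mean = mean, sd = sd, n_pixels = n_pixels),
            class = "background_stats")
}

as_background_stats <- function(bg) {
  if (inherits(bg, "background_stats")) return(bg)
  if (is.list(bg) && all(c("mean", "sd") %in% names(bg))) {
    return(new_background_stats(bg$mean, bg$sd, bg$n_pixels %||% NA_integer_))
  }
  stop("`bg` must be background_stats or list(mean =, sd =)", call. = FALSE)
}

#' Call marker positivity for cell intensities
#'
#' A cell is positive when its mean intensity strictly exceeds background
#' mean + 3 background SD. Vectorized over intensities.
#'
#' @param cell_intensity numeric vector of per-cell mean intensities, a.u.
#' @param bg a [background_stats()] (or `list(mean =, sd =)`)
#' @param k SD multiplier (default 3)
#' @return logical vector
#' @export
#' @examples
#' call_positive(c(15, 16, 16.1), new_background_stats(10, 2))
call_positive <- function(cell_intensity, bg, k = 3) {
  bg <- as_background_stats(bg)
  if (any(!is.finite(cell_intensity))) {
    stop("intensities must be finite", call. = FALSE)
  }
  cell_intensity > bg$mean + k * bg$sd
}

#' Positive-cell fraction per region
#'
#' @param cells cell table: tibble with `region` and one intensity column per
#'   channel
#' @param channel intensity column name
#' @param bg a [background_stats()] for that channel
#' @param regions regions to report; default all present
#' @return tibble: `region`, `n_cells`, `n_positive`, `fraction`
#' @export
region_fraction <- function(cells, channel, bg, regions = NULL) {
  if (!channel %in% names(cells)) {
    stop(sprintf("channel `%s` not in cell table", channel), call. = FALSE)
  }
  if (!is.null(regions)) {
    cells <- dplyr::filter(cells, .data$region %in% regions)
  }
  if (nrow(cells) == 0) {
    return(tibble::tibble(region = character(0), n_cells = integer(0),
                          n_positive = integer(0), fraction = numeric(0)))
  }
  cells |>
    dplyr::mutate(.pos = call_positive(.data[[channel]], bg)) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     n_positive = sum(.data$.pos),
                     fraction = mean(.data$.pos),
                     .groups = "drop")
}

#' Coexpression fraction between two channels
#'
#' Fraction of cells positive for `channel_a` that are also positive for
#' `channel_b`. The denominator is configurable because published
#' coexpression percentages are ambiguous about it: `"a_positive"` (default,
#' b-positives among a-positives) or `"b_positive"`.
#'
#' @param cells cell table with both intensity columns
#' @param channel_a,channel_b intensity column names
#' @param bg_a,bg_b per-channel [background_stats()]
#' @param denominator `"a_positive"` or `"b_positive"`
#' @return a single proportion, or `NA` when the denominator set is empty
#' @export
coexpression_fraction <- function(cells, channel_a, channel_b, bg_a, bg_b,
                                  denominator = c("a_positive",
                                                  "b_positive")) {
  denominator <- match.arg(denominator)
  pos_a <- call_positive(cells[[channel_a]], bg_a)
  pos_b <- call_positive(cells[[channel_b]], bg_b)
  den <- if (denominator == "a_positive") pos_a else pos_b
  if (!any(den)) return(NA_real_)
  mean(pos_a[den] & pos_b[den])
}

#' Plot per-region positive fractions
#'
#' @param fractions a [region_fraction()] result
#' @return a ggplot bar chart
#' @export
plot_region_fractions <- function(fractions) {
  ggplot2::ggplot(fractions,
                  ggplot2::aes(x = .data$region, y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%g%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "positive cells")
}
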