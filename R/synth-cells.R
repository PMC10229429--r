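#' Simulate a per-cell intensity table with known positive fractions
#'
#' Emulates the quantification input of a FISH/IHC experiment: each region
#' contributes `n_cells_per_region` cells; a programmed fraction of them is
#' truly marker-positive and draws its mean intensity from `pos_dist`, the
#' rest from `neg_dist` (truncated normal, floor 0). Background statistics for
#' the positivity threshold (mean + 3 SD of the non-cell background) are
#' returned alongside.
#'
#' @param regions character vector of region labels (e.g. MPA, MPO, Pe, DMH)
#' @param n_cells_per_region cells per region (scalar or per region)
#' @param positive_fraction programmed positive fraction, scalar or named by
#'   region, each in [0, 1]
#' @param pos_dist,neg_dist lists `list(mean =, sd =)` for positive / negative
#'   cell mean intensities, a.u.
#' @param background_mean,background_sd background pixel statistics, a.u.
#' @param channel channel name used as the intensity column
#' @param seed integer seed
#' @return list with `cells` (tibble: cell_id, region, `<channel>`), `truth`
#'   (tibble: cell_id, region, positive; plus `fraction_by_region`), and
#'   `background` (list mean, sd, n_pixels)
#' @export
#' @examples
#' sim <- simulate_cell_table(c("MPA", "MPO"), 100, 0.1, seed = 2)
#' sim$truth$fraction_by_region
simulate_cell_table <- function(regions,
                                n_cells_per_region = 500,
                                positive_fraction = 0.1,
                                pos_dist = list(mean = 60, sd = 8),
                                neg_dist = list(mean = 10, sd = 1.5),
                                background_mean = 10,
                                background_sd = 2,
                                channel = "Fos",
                                seed = 1L) {
  regions <- as.character(regions)
  n_per <- rep_len(as.integer(n_cells_per_region), length(regions))
  frac <- if (!is.null(names(positive_fraction))) {
    unname(positive_fraction[regions])
  } else {
    rep_len(positive_fraction, length(regions))
  }
  if (any(is.na(frac)) || any(frac < 0 | frac > 1)) {
    stop("`positive_fraction` must be in [0, 1] for every region",
         call. = FALSE)
  }
  set.seed(derive_seed(seed))
  rows <- purrr::map(seq_along(regions), function(i) {
    n <- n_per[i]
    pos <- runif(n) < frac[i]
    inten <- ifelse(pos,
                    rnorm(n, pos_dist$mean, pos_dist$sd),
                    rnorm(n, neg_dist$mean, neg_dist$sd))
    tibble::tibble(region = regions[i], positive = pos,
                   intensity = pmax(0, inten))
  })
  df <- dplyr::bind_rows(rows)
  df$cell_id <- sprintf("cell%05d", seq_len(nrow(df)))
  cells <- tibble::tibble(cell_id = df$cell_id, region = df$region)
  cells[[channel]] <- df$intensity
  truth_tbl <- tibble::tibble(cell_id = df$cell_id, region = df$region,
                              positive = df$positive)
  frac_by_region <- truth_tbl |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(fraction = mean(.data$positive), .groups = "drop")
  list(
    cells = cells,
    truth = list(cells = truth_tbl, fraction_by_region = frac_by_region,
                 programmed_fraction = setNames(frac, regions), seed = seed),
    background = list(mean = background_mean, sd = background_sd,
                      n_pixels = NA_integer_)
  )
}
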