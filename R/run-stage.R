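#' Run one pipeline stage from a configuration
#'
#' Reproducible entry point tying the modules together. A configuration is a
#' list (or a YAML file) with exactly the keys `stage`, `seed`, `out_dir`
#' and optionally `params` (stage parameters) and `inputs` (named file
#' paths); unknown keys are rejected by name. The stage runs with the given
#' seed, writes its outputs under `out_dir` and a `manifest.json` recording
#' the configuration, package version, and MD5 checksums of every input and
#' output, so any run can be reproduced from its manifest alone (see
#' [rerun_from_manifest()]).
#'
#' Stages: `synth_plant` (physiology traces as CSV), `synth_photometry`,
#' `synth_cells`, `synth_counts` (MTX trio), `loop` (closed-loop session:
#' samples CSV, schedule CSV, summary JSON), `endpoints` (endpoint JSON from
#' trace CSVs), `photometry` (window stats JSON from a trace CSV and a
#' schedule CSV), `histo` (region fraction JSON from a cell CSV).
#'
#' @param config list or path to a YAML file
#' @return the manifest, invisibly, as a list
#' @export
run_stage <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  allowed <- c("stage", "seed", "out_dir", "params", "inputs")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (req in c("stage", "seed", "out_dir")) {
    if (is.null(config[[req]])) {
      stop("config is missing `", req, "`", call. = FALSE)
    }
  }
  stages <- list(
    synth_plant = stage_synth_plant,
    synth_photometry = stage_synth_photometry,
    synth_cells = stage_synth_cells,
    synth_counts = stage_synth_counts,
    loop = stage_loop,
    endpoints = stage_endpoints,
    photometry = stage_photometry,
    histo = stage_histo
  )
  fn <- stages[[config$stage]]
  if (is.null(fn)) {
    stop("unknown stage `", config$stage, "`; available: ",
         paste(names(stages), collapse = ", "), call. = FALSE)
  }
  for (p in unlist(config$inputs)) {
    if (!file.exists(p)) stop("missing input: ", p, call. = FALSE)
  }
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  outputs <- fn(config$params %||% list(), config$inputs %||% list(),
                config$out_dir, as.integer(config$seed))
  manifest <- list(
    stage = config$stage,
    seed = as.integer(config$seed),
    params = config$params %||% list(),
    package_version = as.character(utils::packageVersion("uihkit")),
    inputs = lapply(unlist(config$inputs), function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    outputs = lapply(outputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    out_dir = config$out_dir
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' @rdname run_stage
#' @param manifest_path path to a `manifest.json` written by [run_stage()]
#' @param out_dir where to re-run; defaults to the manifest's directory
#' @export
rerun_from_manifest <- function(manifest_path, out_dir = NULL) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  inputs <- lapply(man$inputs, `[[`, "path")
  names(inputs) <- names(man$inputs)
  run_stage(list(stage = man$stage, seed = man$seed, params = man$params,
                 inputs = inputs,
                 out_dir = out_dir %||% man$out_dir))
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

stage_synth_plant <- function(params, inputs, out_dir, seed) {
  plant <- do.call(plant_params, params$plant %||% list())
  schedule <- NULL
  if (!is.null(params$train_onsets_s)) {
    tr <- controller_config()$train
    schedule <- dplyr::bind_rows(lapply(seq_along(params$train_onsets_s),
      function(i) build_train(tr, params$train_onsets_s[[i]], i)))
  }
  sim <- simulate_plant(plant, schedule,
                        duration_min = params$duration_min %||% 120,
                        dt_min = params$dt_min %||% 0.05, seed = seed)
  outs <- character(0)
  for (sig in c("t_core", "t_bat", "vo2", "vco2")) {
    p <- file.path(out_dir, paste0(sig, ".csv"))
    write_trace_csv(plant_trace(sim, sig), p)
    outs <- c(outs, p)
  }
  outs
}

stage_synth_photometry <- function(params, inputs, out_dir, seed) {
  sim <- do.call(simulate_photometry, c(params, list(seed = seed)))
  p1 <- file.path(out_dir, "photometry.csv")
  write_trace_csv(sim$trace, p1)
  p2 <- write_json_report(sim$truth, file.path(out_dir, "truth.json"))
  c(p1, p2)
}

stage_synth_cells <- function(params, inputs, out_dir, seed) {
  sim <- do.call(simulate_cell_table, c(params, list(seed = seed)))
  p1 <- file.path(out_dir, "cells.csv")
  readr::write_csv(sim$cells, p1)
  p2 <- write_json_report(sim$background, file.path(out_dir, "background.json"))
  p3 <- write_json_report(
    list(fraction_by_region = sim$truth$fraction_by_region),
    file.path(out_dir, "truth.json"))
  c(p1, p2, p3)
}

stage_synth_counts <- function(params, inputs, out_dir, seed) {
  sim <- do.call(simulate_counts, c(params, list(seed = seed)))
  write_mtx(sim$counts, out_dir)
  p4 <- file.path(out_dir, "labels.csv")
  readr::write_csv(tibble::tibble(barcode = colnames(sim$counts),
                                  cluster = unname(sim$truth$cluster)), p4)
  p5 <- write_json_report(
    list(torpor_clusters = sim$truth$torpor_clusters,
         activated_cluster = sim$truth$activated_cluster),
    file.path(out_dir, "truth.json"))
  c(file.path(out_dir, c("matrix.mtx", "features.tsv", "barcodes.tsv")),
    p4, p5)
}

stage_loop <- function(params, inputs, out_dir, seed) {
  plant <- do.call(plant_params, params$plant %||% list())
  cfg <- do.call(controller_config, params$controller %||% list())
  log <- run_closed_loop(plant, cfg,
                         duration_h = params$duration_h %||% 24,
                         dt_min = params$dt_min %||% 0.1, seed = seed)
  p1 <- file.path(out_dir, "samples.csv")
  readr::write_csv(log$samples, p1)
  p2 <- file.path(out_dir, "schedule.csv")
  readr::write_csv(log$trains, p2)
  p3 <- write_json_report(as.list(summarize_session(log)),
                          file.path(out_dir, "summary.json"))
  c(p1, p2, p3)
}

stage_endpoints <- function(params, inputs, out_dir, seed) {
  t_core <- read_trace_csv(inputs$t_core)
  vo2 <- read_trace_csv(inputs$vo2)
  vco2 <- read_trace_csv(inputs$vco2)
  sim <- tibble::tibble(time_s = t_core$time_s, t_core = t_core$value,
                        vo2 = vo2$value, vco2 = vco2$value)
  rep <- endpoint_report(sim, us_onset = params$us_onset %||% 0)
  write_json_report(rep, file.path(out_dir, "endpoints.json"))
}

stage_photometry <- function(params, inputs, out_dir, seed) {
  trace <- read_trace_csv(inputs$trace)
  schedule <- readr::read_csv(inputs$schedule, show_col_types = FALSE,
                              progress = FALSE)
  z <- zscore(debleach(trace,
                       params$highpass_cutoff_hz %||% 0.01))
  peaks <- detect_peaks(z, params$min_prominence %||% 2)
  stats <- train_window_stats(z, peaks, schedule)
  write_json_report(stats, file.path(out_dir, "photometry_stats.json"))
}

stage_histo <- function(params, inputs, out_dir, seed) {
  cells <- readr::read_csv(inputs$cells, show_col_types = FALSE,
                           progress = FALSE)
  bg <- new_background_stats(params$background_mean, params$background_sd)
  fr <- region_fraction(cells, params$channel %||% "Fos", bg)
  write_json_report(fr, file.path(out_dir, "fractions.json"))
}
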