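#' Trace CSV round-trip
#'
#' Traces are written as RFC-4180 CSV with columns `time_s`, `value`, `unit`
#' (the unit tag repeated per row). Full double precision is preserved, so a
#' write/read round trip is lossless to better than 1e-12.
#'
#' @param trace a trace (data frame with `time_s`, `value`)
#' @param path file path
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv`
#'   returns a [new_trace()]
#' @export
write_trace_csv <- function(trace, path) {
  trace <- as_trace(trace)
  df <- data.frame(time_s = trace$time_s, value = trace$value,
                   unit = trace_unit(trace))
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) stop("empty trace file: ", path, call. = FALSE)
  if (!all(c("time_s", "value") %in% names(df))) {
    stop("trace CSV needs columns time_s, value: ", path, call. = FALSE)
  }
  new_trace(df$time_s, df$value,
            if ("unit" %in% names(df)) df$unit[1] else "au")
}

#' Thermal stack TIFF round-trip
#'
#' Frames are stored as a multi-page 32-bit float TIFF. Because the TIFF
#' writer stores floats on [0, 1], temperatures are written as
#' `(T - offset) / scale` with `offset`/`scale` recorded in the sidecar CSV
#' (`frame_index`, `time_s`, `offset_degC`, `scale_degC`, `pixel_size_mm`);
#' the round trip is accurate to float32 resolution (~1e-5 degC over a
#' typical 40 degC span).
#'
#' @param stack a [thermal_stack()]
#' @param tiff_path output TIFF path
#' @param csv_path sidecar path; default `tiff_path` with `.csv` extension
#' @return `write_thermal_stack` returns the two paths invisibly;
#'   `read_thermal_stack` returns a [thermal_stack()]
#' @export
write_thermal_stack <- function(stack, tiff_path, csv_path = NULL) {
  stopifnot(inherits(stack, "thermal_stack"))
  csv_path <- csv_path %||% sub("\\.tiff?$", ".csv", tiff_path)
  rng <- range(unlist(lapply(stack$frames, range)))
  offset <- rng[1]
  scale <- max(rng[2] - rng[1], 1e-9)
  norm <- lapply(stack$frames, function(f) (f - offset) / scale)
  tiff::writeTIFF(norm, tiff_path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  side <- data.frame(frame_index = seq_along(stack$frames),
                     time_s = stack$time_s,
                     offset_degC = offset, scale_degC = scale,
                     pixel_size_mm = stack$pixel_size_mm)
  readr::write_csv(side, csv_path)
  invisible(c(tiff = tiff_path, csv = csv_path))
}

#' @rdname write_thermal_stack
#' @export
read_thermal_stack <- function(tiff_path, csv_path = NULL) {
  csv_path <- csv_path %||% sub("\\.tiff?$", ".csv", tiff_path)
  side <- readr::read_csv(csv_path, show_col_types = FALSE, progress = FALSE)
  frames <- tiff::readTIFF(tiff_path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    f * side$scale_degC[1] + side$offset_degC[1]
  })
  thermal_stack(frames, side$time_s, side$pixel_size_mm[1])
}

#' Sparse count matrix MTX round-trip
#'
#' MatrixMarket `matrix.mtx` with `features.tsv` / `barcodes.tsv` sidecars,
#' the 10x-style on-disk layout. Integer counts round-trip exactly and the
#' sparsity pattern is preserved.
#'
#' @param m genes x cells sparse matrix with dimnames
#' @param dir output directory (created if missing)
#' @return `write_mtx` returns `dir` invisibly; `read_mtx` returns a
#'   `dgCMatrix` with dimnames
#' @export
write_mtx <- function(m, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(m, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname write_mtx
#' @export
read_mtx <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop("no matrix.mtx under ", dir, call. = FALSE)
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "features.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  m
}
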