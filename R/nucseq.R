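#' Quality-control thresholds for nuclei
#'
#' The filtering rules: cells with *more than* `mito_max` mitochondrial
#' fraction are removed (contamination), cells with feature counts *above*
#' `features_max` (doublets/multiplets) or *below* `features_min` are
#' removed. All removals are strict, so boundary cells (exactly 5%
#' mitochondrial, exactly 200 or 7,500 features) are kept.
#'
#' @param mito_max maximum mitochondrial count fraction (default 0.05)
#' @param features_max,features_min detected-gene bounds (defaults 7500, 200)
#' @return list of class `qc_thresholds`
#' @export
qc_thresholds <- function(mito_max = 0.05, features_max = 7500,
                          features_min = 200) {
  assert_number(mito_max, "mito_max", 0, 1)
  assert_number(features_min, "features_min", 0)
  assert_number(features_max, "features_max", 0)
  if (features_min >= features_max) {
    stop("`features_min` must be below `features_max`", call. = FALSE)
  }
  structure(list(mito_max = mito_max, features_max = features_max,
                 features_min = features_min), class = "qc_thresholds")
}

#' Per-cell mitochondrial count fraction
#'
#' Fraction of each cell's counts on genes whose name starts with `mt-`
#' (case-insensitive). Zero-count cells get fraction 0.
#'
#' @param m genes x cells count matrix (dgCMatrix or matrix) with rownames
#' @return named numeric vector, one fraction per cell
#' @export
mito_fraction <- function(m) {
  mito <- grepl("^mt-", rownames(m), ignore.case = TRUE)
  tot <- Matrix::colSums(m)
  mt <- Matrix::colSums(m[mito, , drop = FALSE])
  ifelse(tot > 0, mt / tot, 0)
}

#' Filter cells by QC thresholds
#'
#' Keeps the cells passing every rule of [qc_thresholds()] and reports how
#' many cells each rule removed (a cell may violate several rules).
#' Idempotent: filtering a filtered matrix removes nothing further.
#'
#' @param m genes x cells count matrix with dimnames
#' @param thr a [qc_thresholds()]
#' @return list: `counts` (filtered matrix), `report` (tibble: rule,
#'   n_removed), `kept` (logical per input cell)
#' @export
#' @examples
#' sim <- simulate_counts(n_cells = 100, n_genes = 300, seed = 1)
#' qc <- qc_filter(sim$counts)
#' qc$report
qc_filter <- function(m, thr = qc_thresholds()) {
  stopifnot(inherits(thr, "qc_thresholds"))
  mito <- mito_fraction(m)
  nfeat <- Matrix::colSums(m > 0)
  bad_mito <- mito > thr$mito_max
  bad_hi <- nfeat > thr$features_max
  bad_lo <- nfeat < thr$features_min
  keep <- !(bad_mito | bad_hi | bad_lo)
  if (!any(keep)) {
    warning("all cells removed by QC", call. = FALSE)
  }
  list(
    counts = m[, keep, drop = FALSE],
    report = tibble::tibble(
      rule = c("mito_fraction", "features_above_max", "features_below_min"),
      n_removed = c(sum(bad_mito), sum(bad_hi), sum(bad_lo))
    ),
    kept = setNames(keep, colnames(m))
  )
}

#' Log-normalize a count matrix
#'
#' Per cell: `log(1 + count / cell_total * scale)` with natural log and a
#' scale factor of 10,000 -- the standard global-scaling normalization.
#' Preserves the zero pattern exactly.
#'
#' @param m genes x cells count matrix; every cell must have positive total
#' @param scale scale factor (default 1e4)
#' @return normalized matrix of the same class/sparsity
#' @export
lognormalize <- function(m, scale = 1e4) {
  tot <- Matrix::colSums(m)
  if (any(tot <= 0)) stop("every cell must have a positive total count",
                          call. = FALSE)
  if (inherits(m, "CsparseMatrix")) {
    out <- m
    cell_of <- rep(seq_len(ncol(m)), diff(m@p))
    out@x <- log1p(m@x / tot[cell_of] * scale)
    out
  } else {
    log1p(sweep(as.matrix(m), 2, tot, "/") * scale)
  }
}

#' The packaged immediate-early-gene exclusion list
#'
#' A curated default list of 139 mouse immediate-early-gene symbols, used to
#' exclude activation-driven genes from variable-feature selection so that
#' stimulation state does not dominate the clustering space. The list is a
#' package-curated stand-in for published IEG catalogues and is replaceable:
#' pass any character vector to [select_variable_features()] instead.
#'
#' @param path optional path to a one-column TSV of gene symbols (header
#'   `gene`); default the packaged list
#' @return character vector of gene symbols
#' @export
ieg_list <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ieg_default.tsv",
                                package = "uihkit", mustWork = TRUE)
  utils::read.delim(path, header = TRUE)$gene
}

#' Select top variable features, excluding IEGs
#'
#' Ranks genes by dispersion (variance / mean of the normalized values;
#' genes with zero mean get dispersion 0) after removing every gene on the
#' exclusion list, and returns the top `n`. Ties break by input gene order.
#'
#' @param normalized genes x cells normalized matrix with rownames
#' @param n number of features (default 4000)
#' @param exclude gene symbols to drop before ranking; default [ieg_list()]
#' @return character vector of at most `n` gene names; shorter with a
#'   warning when fewer candidates exist
#' @export
select_variable_features <- function(normalized, n = 4000,
                                     exclude = ieg_list()) {
  genes <- rownames(normalized)
  if (is.null(genes)) stop("matrix must have gene rownames", call. = FALSE)
  cand <- !(genes %in% exclude)
  mu <- Matrix::rowMeans(normalized)
  ex2 <- Matrix::rowMeans(normalized^2)
  nc <- ncol(normalized)
  v <- (ex2 - mu^2) * nc / max(1, nc - 1)
  disp <- ifelse(mu > 0, pmax(0, v) / mu, 0)
  idx <- which(cand)
  if (length(idx) < n) {
    warning(sprintf("only %d candidate genes for n = %d", length(idx), n),
            call. = FALSE)
    n <- length(idx)
  }
  ord <- idx[order(-disp[idx])]
  genes[ord[seq_len(n)]]
}

#' Mean expression profiles per cluster
#'
#' @param normalized genes x cells normalized matrix with dimnames
#' @param labels per-cell cluster labels (named or in column order)
#' @param genes genes to profile
#' @return tibble: `cluster` plus one column per gene (mean normalized
#'   expression)
#' @export
cluster_profiles <- function(normalized, labels, genes) {
  miss <- setdiff(genes, rownames(normalized))
  if (length(miss)) {
    stop("genes not in matrix: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  labels <- as.character(labels)
  sub <- as.matrix(normalized[genes, , drop = FALSE])
  cl <- sort(unique(labels))
  prof <- t(vapply(cl, function(g) {
    rowMeans(sub[, labels == g, drop = FALSE])
  }, numeric(length(genes))))
  colnames(prof) <- genes
  dplyr::bind_cols(tibble::tibble(cluster = cl), tibble::as_tibble(prof))
}

#' Identify torpor-associated clusters by marker k-means
#'
#' k-means (k = 2 by default) on the per-cluster mean expression of the
#' torpor markers Adcyap1, Qrfp and Esr1; the centroid with the higher mean
#' marker expression defines the torpor-associated cluster set. Seeded
#' deterministic initialization with multiple restarts.
#'
#' @param profiles a [cluster_profiles()] tibble over the torpor markers
#' @param k number of k-means groups (default 2: torpor vs not)
#' @param seed integer seed
#' @param n_restarts k-means restarts
#' @return character vector of torpor-associated cluster names
#' @export
torpor_kmeans <- function(profiles, k = 2, seed = 1L, n_restarts = 10) {
  x <- as.matrix(profiles[, setdiff(names(profiles), "cluster")])
  rownames(x) <- profiles$cluster
  if (nrow(x) < k) stop("k exceeds the number of clusters", call. = FALSE)
  if (nrow(unique(x)) < k) {
    warning("fewer distinct profiles than k; returning all clusters as one ",
            "degenerate group", call. = FALSE)
    return(profiles$cluster)
  }
  set.seed(derive_seed(seed))
  km <- stats::kmeans(x, centers = k, nstart = n_restarts)
  top <- which.max(rowMeans(km$centers))
  profiles$cluster[km$cluster == top]
}

#' Rank torpor clusters by immediate-early-gene activation
#'
#' Each IEG column is z-scored across all clusters (sample SD; constant
#' columns contribute 0); a cluster's activation score is the mean z across
#' the IEG panel. Clusters in `torpor_set` are returned ranked by descending
#' score; the top cluster is the ultrasound-activated candidate. Exact ties
#' are flagged and broken by cluster name.
#'
#' @param profiles a [cluster_profiles()] tibble over [activation_iegs]
#' @param torpor_set cluster names from [torpor_kmeans()]
#' @return tibble: `cluster`, `score`, `rank`, `tie`; attribute
#'   `activated` = top cluster name
#' @export
ieg_activation_rank <- function(profiles, torpor_set) {
  if (length(torpor_set) == 0) stop("`torpor_set` is empty", call. = FALSE)
  x <- as.matrix(profiles[, setdiff(names(profiles), "cluster")])
  z <- apply(x, 2, function(col) {
    s <- sd(col)
    if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  score <- rowMeans(z)
  sel <- profiles$cluster %in% torpor_set
  out <- tibble::tibble(cluster = profiles$cluster[sel],
                        score = score[sel])
  out <- dplyr::arrange(out, dplyr::desc(.data$score), .data$cluster)
  out$rank <- seq_len(nrow(out))
  out$tie <- duplicated(out$score) | duplicated(out$score, fromLast = TRUE)
  attr(out, "activated") <- out$cluster[1]
  out
}

#' Classify clusters as excitatory, inhibitory, hybrid or unassigned
#'
#' By mean normalized expression of Slc17a6 (excitatory) and Gad1
#' (inhibitory) against a detection threshold: one above -> that class, both
#' above -> hybrid, neither -> unassigned.
#'
#' @param profiles a [cluster_profiles()] tibble over [class_markers]
#' @param threshold detection threshold on mean normalized expression
#' @return tibble: `cluster`, `label`
#' @export
classify_excitatory_inhibitory <- function(profiles, threshold = 0.5) {
  exc <- profiles[[class_markers[["excitatory"]]]] > threshold
  inh <- profiles[[class_markers[["inhibitory"]]]] > threshold
  tibble::tibble(
    cluster = profiles$cluster,
    label = dplyr::case_when(exc & inh ~ "hybrid",
                             exc ~ "excitatory",
                             inh ~ "inhibitory",
                             TRUE ~ "unassigned")
  )
}

#' Full rule-based annotation of a count matrix
#'
#' QC filter, log-normalize, profile the torpor markers and IEGs per
#' (externally supplied) cluster, find the torpor-associated set by k-means
#' and rank it by IEG activation.
#'
#' @param counts genes x cells count matrix with dimnames
#' @param labels per-cell cluster labels, aligned with the columns of
#'   `counts`
#' @param thr a [qc_thresholds()]
#' @param k torpor k-means k
#' @param seed integer seed
#' @return list: `activated` (top cluster name), `torpor_set`, `ranking`
#'   tibble, `qc_report`, `n_cells_kept`
#' @export
annotate_torpor_clusters <- function(counts, labels, thr = qc_thresholds(),
                                     k = 2, seed = 1L) {
  qc <- qc_filter(counts, thr)
  labels <- labels[qc$kept]
  norm <- lognormalize(qc$counts)
  prof_markers <- cluster_profiles(norm, labels, torpor_markers)
  prof_iegs <- cluster_profiles(norm, labels, activation_iegs)
  torpor_set <- torpor_kmeans(prof_markers, k = k, seed = seed)
  ranking <- ieg_activation_rank(prof_iegs, torpor_set)
  list(activated = attr(ranking, "activated"),
       torpor_set = torpor_set,
       ranking = ranking,
       qc_report = qc$report,
       n_cells_kept = ncol(qc$counts))
}
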