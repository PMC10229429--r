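make_counts <- function(mat, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- sprintf("Gene%03d", seq_len(nrow(mat)))
  if (is.null(cells)) cells <- sprintf("cell%03d", seq_len(ncol(mat)))
  m <- Matrix::Matrix(mat, sparse = TRUE)
  dimnames(m) <- list(genes, cells)
  methods::as(m, "CsparseMatrix")
}

test_that("qc_filter applies the strict removal rules with kept boundaries", {
  # 4 genes incl one mito; craft cells at and beyond each boundary
  genes <- c("mt-Nd1", "GeneA", "GeneB", "GeneC")
  m <- make_counts(cbind(
    c(5, 95, 0, 0),     # mito exactly 5% -> kept
    c(6, 94, 0, 0),     # mito 6% -> removed
    c(0, 10, 10, 0),    # 2 features with floor 2 -> see thresholds below
    c(0, 5, 5, 5)       # 3 features
  ), genes = genes)
  thr <- qc_thresholds(mito_max = 0.05, features_max = 3, features_min = 2)
  qc <- qc_filter(m, thr)
  expect_true(qc$kept[[1]])    # boundary mito kept
  expect_false(qc$kept[[2]])
  expect_true(qc$kept[[3]])    # features_min boundary kept
  expect_true(qc$kept[[4]])    # features_max boundary kept
  expect_equal(qc$report$n_removed[qc$report$rule == "mito_fraction"], 1)

  # a cell with 150 detected genes is removed under the default 200 floor
  big <- make_counts(matrix(c(rep(1, 150), rep(0, 150)), ncol = 1),
                     genes = sprintf("G%03d", 1:300))
  expect_warning(qc2 <- qc_filter(big), "all cells removed")
  expect_equal(ncol(qc2$counts), 0)
})

test_that("qc_filter is idempotent and equals brute-force evaluation", {
  sim <- simulate_counts(n_cells = 400, n_genes = 300, mito_mean = 0.05,
                         mito_kappa = 20, seed = 2)
  thr <- qc_thresholds(mito_max = 0.05, features_max = 200, features_min = 50)
  qc1 <- qc_filter(sim$counts, thr)
  qc2 <- qc_filter(qc1$counts, thr)
  expect_identical(dim(qc2$counts), dim(qc1$counts))
  expect_equal(sum(qc2$report$n_removed), 0)

  dense <- as.matrix(sim$counts)
  mito_rows <- grepl("^mt-", rownames(dense))
  want_keep <- vapply(seq_len(ncol(dense)), function(j) {
    cell <- dense[, j]
    mf <- sum(cell[mito_rows]) / sum(cell)
    nf <- sum(cell > 0)
    mf <= 0.05 && nf >= 50 && nf <= 200
  }, logical(1))
  expect_identical(unname(qc1$kept), want_keep)
})

test_that("lognormalize matches hand arithmetic and preserves structure", {
  m <- make_counts(cbind(c(10, 9990, 0), c(1, 1, 2)))
  n <- lognormalize(m, scale = 1e4)
  expect_equal(n[1, 1], log(11))                # 10 of 10,000 at scale 1e4
  expect_equal(n[3, 1], 0)                      # zeros stay zero
  doubled <- lognormalize(make_counts(cbind(c(20, 19980, 0))), scale = 1e4)
  expect_equal(as.numeric(doubled[, 1]), as.numeric(n[, 1]),
               tolerance = 1e-12)               # depth invariance
  expect_identical(as.logical(n == 0), as.logical(m == 0))
  empty <- make_counts(cbind(c(0, 0, 0)))
  expect_error(lognormalize(empty), "positive total")
})

test_that("variable-feature selection ranks by dispersion and drops IEGs", {
  set.seed(77)
  n_cells <- 60
  genes <- c("Fos", sprintf("G%02d", 1:49))
  vals <- matrix(rpois(50 * n_cells, 2), 50, n_cells)
  vals[1, ] <- rpois(n_cells, 50)               # Fos highly variable
  vals[2, ] <- 3                                 # G01 constant
  m <- make_counts(vals, genes = genes)
  norm <- lognormalize(m)
  sel <- select_variable_features(norm, n = 10, exclude = "Fos")
  expect_false("Fos" %in% sel)
  expect_false("G01" %in% sel[1:9])   # constant gene never beats variable ones

  # brute-force dispersion ranking on the same matrix
  dense <- as.matrix(norm)
  disp <- apply(dense, 1, function(x) if (mean(x) > 0) var(x) / mean(x) else 0)
  cand <- setdiff(genes, "Fos")
  want <- cand[order(-disp[cand])][1:10]
  expect_identical(sel, want)

  expect_warning(all_feats <- select_variable_features(norm, n = 100,
                                                       exclude = "Fos"),
                 "candidate")
  expect_equal(length(all_feats), 49)
})

test_that("the packaged IEG list has 139 genes including the activation panel", {
  iegs <- ieg_list()
  expect_equal(length(iegs), 139)
  expect_true(all(activation_iegs %in% iegs))
  expect_false(any(duplicated(iegs)))
  norm <- lognormalize(simulate_counts(n_cells = 50, n_genes = 100,
                                       seed = 1)$counts)
  sel <- select_variable_features(norm, n = 20)
  expect_false(any(sel %in% iegs))
})

test_that("torpor_kmeans separates well-split marker profiles exactly", {
  prof <- tibble::tibble(
    cluster = c("e0", "e1", "h0", "i0", "i1"),
    Adcyap1 = c(2.5, 2.2, 2.8, 0.1, 0.2),
    Qrfp = c(1.8, 2.0, 2.2, 0.05, 0.1),
    Esr1 = c(2.1, 2.4, 1.9, 0.2, 0.1)
  )
  got <- sort(torpor_kmeans(prof, seed = 1))
  expect_identical(got, c("e0", "e1", "h0"))
  # label permutation of input rows leaves the returned set unchanged
  got2 <- sort(torpor_kmeans(prof[c(4, 2, 5, 1, 3), ], seed = 1))
  expect_identical(got2, got)

  flat <- prof
  flat[, -1] <- 1
  expect_warning(all_cl <- torpor_kmeans(flat, seed = 1), "degenerate")
  expect_equal(sort(all_cl), sort(prof$cluster))
  expect_error(torpor_kmeans(prof[1, ], k = 2), "k exceeds")
})

test_that("IEG ranking scores by mean z across the panel with stable ties", {
  prof <- tibble::tibble(
    cluster = c("a", "b", "c"),
    Fos = c(3, 1, 1), Fosb = c(2.5, 1, 1), Nr4a1 = c(4, 2, 2),
    Egr1 = c(3, 1.5, 1.5), Dusp1 = c(2, 0.5, 0.5)
  )
  rk <- ieg_activation_rank(prof, c("a", "b", "c"))
  expect_equal(rk$cluster[1], "a")
  expect_equal(attr(rk, "activated"), "a")
  expect_true(all(rk$tie[rk$cluster %in% c("b", "c")]))
  expect_false(rk$tie[rk$cluster == "a"])
  # brute-force score computation
  x <- as.matrix(prof[, -1])
  z <- scale(x)
  z[is.nan(z)] <- 0
  expect_equal(rk$score[match(prof$cluster, rk$cluster)],
               unname(rowMeans(z)), tolerance = 1e-12)
  expect_error(ieg_activation_rank(prof, character(0)), "empty")
})

test_that("excitatory/inhibitory labels follow the marker thresholds", {
  prof <- tibble::tibble(cluster = c("e", "i", "h", "u"),
                         Slc17a6 = c(2, 0.01, 1.5, 0.1),
                         Gad1 = c(0.02, 2.5, 1.2, 0.2))
  lab <- classify_excitatory_inhibitory(prof)
  expect_equal(lab$label, c("excitatory", "inhibitory", "hybrid",
                            "unassigned"))
  # threshold sweep is monotone: higher threshold never adds labels
  n_assigned <- vapply(seq(0, 3, by = 0.1), function(th) {
    sum(classify_excitatory_inhibitory(prof, th)$label != "unassigned")
  }, numeric(1))
  expect_true(all(diff(n_assigned) <= 0))
})

test_that("planted activated cluster is recovered through the full rule chain", {
  hits <- 0
  for (seed in 1:15) {
    sim <- simulate_counts(n_cells = 600, n_genes = 400, seed = seed)
    ann <- annotate_torpor_clusters(sim$counts, sim$truth$cluster,
                                    thr = qc_thresholds(features_min = 0),
                                    seed = seed)
    hits <- hits + (identical(ann$activated, sim$truth$activated_cluster) &&
                      setequal(ann$torpor_set, sim$truth$torpor_clusters))
  }
  expect_gte(hits, 14)
})
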