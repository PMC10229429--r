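#' Marker gene sets used throughout the snRNA-seq rules
#'
#' Torpor-associated neuron markers, the five neuronal-activation
#' immediate-early genes used for activated-cluster ranking, and the
#' excitatory/inhibitory class markers.
#' @name marker_sets
NULL

#' @rdname marker_sets
#' @export
torpor_markers <- c("Adcyap1", "Qrfp", "Esr1")

#' @rdname marker_sets
#' @export
activation_iegs <- c("Fos", "Fosb", "Nr4a1", "Egr1", "Dusp1")

#' @rdname marker_sets
#' @export
class_markers <- c(excitatory = "Slc17a6", inhibitory = "Gad1")

mito_gene_names <- paste0("mt-", c("Nd1", "Nd2", "Co1", "Co2", "Atp6", "Cytb"))

#' Default synthetic cluster specification
#'
#' Eight neuronal clusters: three torpor-associated excitatory clusters (one
#' of which is the ultrasound-activated cluster with elevated IEGs), two
#' plain excitatory and three inhibitory clusters.
#'
#' @return tibble with columns cluster, prop, class, torpor, activated
#' @export
default_cluster_spec <- function() {
  tibble::tibble(
    cluster = c("e0", "e1", "h0", "e2", "e3", "i0", "i1", "i2"),
    prop = c(0.10, 0.10, 0.08, 0.14, 0.14, 0.16, 0.14, 0.14),
    class = c("excitatory", "excitatory", "excitatory", "excitatory",
              "excitatory", "inhibitory", "inhibitory", "inhibitory"),
    torpor = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    activated = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
}

#' Simulate a sparse gene-by-cell count matrix with planted cluster structure
#'
#' Generates Poisson counts over a gene panel that contains the torpor
#' markers, the activation IEGs, the excitatory/inhibitory class markers, a
#' few mitochondrial (`mt-`) genes and filler genes. Torpor clusters carry
#' `marker_fold`-elevated torpor-marker means; the activated cluster carries
#' `ieg_fold`-elevated IEG means. Per-cell sequencing depth is lognormal;
#' per-cell mitochondrial contamination targets a Beta-distributed fraction.
#'
#' @param n_cells number of cells
#' @param n_genes total genes (>= the named panel size)
#' @param cluster_spec tibble as from [default_cluster_spec()]; `prop` is
#'   normalized internally
#' @param marker_base_mean baseline torpor-marker mean count
#' @param marker_fold fold-elevation of torpor markers in torpor clusters
#' @param ieg_base_mean baseline IEG mean count
#' @param ieg_fold fold-elevation of IEGs in the activated cluster
#' @param class_marker_mean mean count of the matching class marker
#' @param base_mean_log,base_sd_log lognormal parameters of filler-gene means
#' @param depth_sd_log lognormal SD of per-cell depth factors
#' @param mito_mean,mito_kappa Beta mean / concentration of the per-cell
#'   target mitochondrial fraction
#' @param seed integer seed
#' @return list with `counts` (a `dgCMatrix`, genes x cells, dimnames set)
#'   and `truth` (per-cell `cluster` labels, `torpor_clusters`,
#'   `activated_cluster`, `cluster_spec`, `seed`)
#' @export
#' @examples
#' sim <- simulate_counts(n_cells = 200, n_genes = 300, seed = 1)
#' dim(sim$counts)
#' sim$truth$activated_cluster
simulate_counts <- function(n_cells = 3000,
                            n_genes = 2000,
                            cluster_spec = default_cluster_spec(),
                            marker_base_mean = 0.4,
                            marker_fold = 8,
                            ieg_base_mean = 0.3,
                            ieg_fold = 8,
                            class_marker_mean = 3,
                            base_mean_log = log(0.35),
                            base_sd_log = 1,
                            depth_sd_log = 0.3,
                            mito_mean = 0.02,
                            mito_kappa = 60,
                            seed = 1L) {
  spec <- as.data.frame(cluster_spec)
  needed <- c("cluster", "prop", "class", "torpor", "activated")
  if (!all(needed %in% names(spec))) {
    stop("`cluster_spec` needs columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  named <- c(torpor_markers, activation_iegs, unname(class_markers),
             mito_gene_names)
  if (n_genes < length(named) + 1) {
    stop("`n_genes` too small for the named gene panel", call. = FALSE)
  }
  genes <- c(named,
             sprintf("Gene%04d", seq_len(n_genes - length(named))))

  set.seed(derive_seed(seed))
  k <- nrow(spec)
  labels <- sample(spec$cluster, n_cells, replace = TRUE,
                   prob = spec$prop / sum(spec$prop))

  # genes x clusters mean matrix
  mu <- matrix(0, n_genes, k, dimnames = list(genes, spec$cluster))
  filler <- setdiff(genes, named)
  mu[filler, ] <- exp(rnorm(length(filler), base_mean_log, base_sd_log))
  mu[torpor_markers, ] <- marker_base_mean
  mu[torpor_markers, spec$torpor] <- marker_base_mean * marker_fold
  mu[activation_iegs, ] <- ieg_base_mean
  mu[activation_iegs, spec$activated] <- ieg_base_mean * ieg_fold
  mu[class_markers[["excitatory"]], ] <-
    ifelse(spec$class == "excitatory", class_marker_mean, 0.02)
  mu[class_markers[["inhibitory"]], ] <-
    ifelse(spec$class == "inhibitory", class_marker_mean, 0.02)

  nonmito_total <- colSums(mu)         # per cluster
  depth <- exp(rnorm(n_cells, 0, depth_sd_log))
  mito_target <- stats::rbeta(n_cells, mito_mean * mito_kappa,
                              (1 - mito_mean) * mito_kappa)

  cl_idx <- match(labels, spec$cluster)
  mito_rows <- match(mito_gene_names, genes)
  # mitochondrial genes: per-cell mean chosen to hit the target fraction in
  # expectation, split evenly across the mt- panel
  mito_mu_cell <- mito_target / (1 - mito_target) *
    nonmito_total[cl_idx] * depth / length(mito_gene_names)

  # draw per cluster block to keep allocations linear in the matrix size
  counts <- matrix(0L, n_genes, n_cells,
                   dimnames = list(genes, sprintf("cell%05d", seq_len(n_cells))))
  for (k in seq_len(nrow(spec))) {
    cells_k <- which(cl_idx == k)
    if (!length(cells_k)) next
    lam <- outer(mu[, k], depth[cells_k])
    lam[mito_rows, ] <- rep(mito_mu_cell[cells_k],
                            each = length(mito_rows))
    counts[, cells_k] <- rpois(length(lam), lam)
  }
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")

  list(
    counts = counts,
    truth = list(
      cluster = setNames(labels, colnames(counts)),
      torpor_clusters = spec$cluster[spec$torpor],
      activated_cluster = spec$cluster[spec$activated][1],
      cluster_spec = tibble::as_tibble(spec),
      mito_target = mito_target,
      seed = seed
    )
  )
}
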