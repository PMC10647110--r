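#' Two-moons synthetic dataset
#'
#' Two interweaving half circles in 2-D: the upper arc of the unit
#' circle and a mirrored arc shifted by `(1, -0.5)`, each with
#' `n_per_class` points, plus isotropic Gaussian noise. The
#' construction (arc layout, shuffling, noise stream) reproduces the
#' canonical scikit-learn `make_moons` output bit-for-bit for the same
#' `noise` and `random_state`, so results line up exactly with the
#' Python fixture; the generator carries its own Mersenne-Twister
#' stream and does not touch the session RNG.
#'
#' @param n_per_class points per half circle.
#' @param noise standard deviation of the added Gaussian noise.
#' @param seed generator seed (`random_state`).
#' @param shuffle randomly permute the points (the canonical default).
#' @return A [labeled_matrix] with 2 features (`x`, `y`) and labels
#'   `0`/`1` per arc.
#' @export
make_two_moons <- function(n_per_class = 2000L, noise = 0.05, seed = 42L,
                           shuffle = TRUE) {
  stopifnot(n_per_class >= 1, noise >= 0)
  res <- cpp_make_moons(as.integer(n_per_class), as.integer(n_per_class),
                        noise, as.integer(seed), shuffle)
  colnames(res$x) <- c("x", "y")
  labeled_matrix(res$x, labels = res$y)
}

#' Synthetic negative-binomial count matrix with planted structure
#'
#' Cells are assigned uniformly to `n_groups` expression groups and
#' `n_batches` technical batches; counts are drawn from
#' `NB(mean, r)` with
#' `mean = exp(log(base_mean) + group_logfc + batch_logfc)`.
#' By default each group up/down-regulates a random 10% of genes by
#' `|log fc| = 1.5` and each batch beyond the first shifts a random 25%
#' of genes by `|log fc| = 1`, a regime in which the groups are
#' recoverable from a PCA + k-means baseline while batch effects, when
#' present, visibly confound it.
#'
#' @param n_cells,n_genes matrix size.
#' @param n_groups,n_batches planted structure.
#' @param group_logfc optional `n_groups` x `n_genes` matrix of group
#'   effects; generated when omitted.
#' @param batch_logfc optional `n_batches` x `n_genes` matrix of batch
#'   shifts; generated when omitted (all zero when `n_batches == 1`).
#' @param base_mean optional per-gene base means; default log-normal
#'   around 2.
#' @param dispersion per-gene NB dispersion `r` (recycled).
#' @param frac_de fraction of genes perturbed per group.
#' @param lfc_de absolute group log-fold change.
#' @param frac_batch fraction of genes shifted per batch.
#' @param lfc_batch absolute batch log-fold change.
#' @param seed RNG seed; the generator is a pure function of its
#'   arguments.
#' @return A [labeled_matrix] with sparse counts, group labels and a
#'   categorical `batch` covariate (when `n_batches > 1`).
#' @export
make_synth_counts <- function(n_cells = 5000L, n_genes = 800L,
                              n_groups = 4L, n_batches = 1L,
                              group_logfc = NULL, batch_logfc = NULL,
                              base_mean = NULL, dispersion = 2,
                              frac_de = 0.1, lfc_de = 1.5,
                              frac_batch = 0.25, lfc_batch = 1,
                              seed = 0L) {
  set.seed(seed)
  base_mean <- base_mean %||% exp(rnorm(n_genes, mean = log(2), sd = 1))
  stopifnot(length(base_mean) == n_genes, all(base_mean > 0))
  r <- rep(dispersion, length.out = n_genes)
  stopifnot(all(r > 0))

  if (is.null(group_logfc)) {
    group_logfc <- matrix(0, n_groups, n_genes)
    n_de <- max(1L, round(frac_de * n_genes))
    for (g in seq_len(n_groups)) {
      idx <- sample.int(n_genes, n_de)
      group_logfc[g, idx] <- sample(c(-lfc_de, lfc_de), n_de, replace = TRUE)
    }
  }
  if (is.null(batch_logfc)) {
    batch_logfc <- matrix(0, n_batches, n_genes)
    if (n_batches > 1) {
      n_b <- max(1L, round(frac_batch * n_genes))
      for (b in 2:n_batches) {
        idx <- sample.int(n_genes, n_b)
        batch_logfc[b, idx] <- sample(c(-lfc_batch, lfc_batch), n_b,
                                      replace = TRUE)
      }
    }
  }
  stopifnot(dim(group_logfc) == c(n_groups, n_genes),
            dim(batch_logfc) == c(n_batches, n_genes))

  group <- sample.int(n_groups, n_cells, replace = TRUE)
  batch <- sample.int(n_batches, n_cells, replace = TRUE)
  logmu <- matrix(log(base_mean), n_cells, n_genes, byrow = TRUE) +
    group_logfc[group, , drop = FALSE] + batch_logfc[batch, , drop = FALSE]
  counts <- matrix(rnbinom(n_cells * n_genes,
                           size = rep(r, each = n_cells),
                           mu = exp(as.numeric(logmu))),
                   n_cells, n_genes)
  cov <- if (n_batches > 1)
    data.frame(batch = factor(paste0("batch", batch))) else NULL
  labeled_matrix(Matrix::Matrix(counts, sparse = TRUE),
                 sample_ids = sprintf("cell_%d", seq_len(n_cells)),
                 feature_ids = sprintf("gene_%d", seq_len(n_genes)),
                 labels = group, covariates = cov)
}
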