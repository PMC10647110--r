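#' Adjusted Rand index
#'
#' Chance-adjusted agreement between two partitions, computed from the
#' contingency table. Invariant to label permutations; 1 iff the
#' partitions are identical up to relabeling; can reach -0.5 for
#' maximally discordant partitions.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return Scalar in `[-0.5, 1]`.
#' @export
ari <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  n <- length(a)
  if (n < 2) stop("need at least two samples")
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1) # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Normalized mutual information
#'
#' Mutual information between two partitions normalized by the
#' arithmetic mean of their entropies. In `[0, 1]`; 1 iff the
#' partitions are identical up to relabeling (including the trivial
#' single-cluster case on both sides); 0 when either side alone is a
#' single cluster while the other is not.
#'
#' @inheritParams ari
#' @return Scalar in `[0, 1]`.
#' @export
nmi <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  n <- length(a)
  tab <- table(a, b)
  pij <- tab / n
  pa <- rowSums(pij)
  pb <- colSums(pij)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 && hb == 0) return(1) # identical trivial partitions
  if (ha == 0 || hb == 0) return(0)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pa, pb)[nz]))
  mi / ((ha + hb) / 2)
}

#' Density-based clustering (DBSCAN)
#'
#' Classic DBSCAN on Euclidean distances: core points have at least
#' `min_samples` neighbours (self included) within `eps`; clusters are
#' the connected components of core points, with border points attached
#' to a neighbouring core's cluster. Noise points are reported as
#' cluster `0` (one shared label).
#'
#' @param Z numeric matrix (samples x dimensions).
#' @param eps neighbourhood radius.
#' @param min_samples density threshold.
#' @param D optional precomputed distance matrix (reused across a grid).
#' @return Integer cluster labels (`0` = noise).
#' @export
dbscan_cluster <- function(Z, eps, min_samples, D = NULL) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (is.null(D)) D <- as.matrix(dist(Z))
  nb <- D <= eps
  core <- rowSums(nb) >= min_samples
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    front <- i
    repeat {
      # expand through core points only; border points are absorbed but
      # do not propagate
      corefront <- front[core[front]]
      if (!length(corefront)) break
      reach <- colSums(nb[corefront, , drop = FALSE]) > 0
      cand <- which(reach & labels == 0L)
      if (!length(cand)) break
      labels[cand] <- cl
      front <- cand
    }
  }
  labels
}

#' Clustering-based embedding evaluation
#'
#' Clusters an embedding with k-means (`k = k_true`, 10 seeded
#' restarts) and with DBSCAN over a parameter grid, scores every run by
#' the average of ARI and NMI against the reference labels, and returns
#' the best run. DBSCAN noise points share one distinct cluster label
#' before scoring.
#'
#' @param Z embedding matrix (samples x dimensions) or `savae_fit`.
#' @param labels reference labels.
#' @param k_true number of clusters for k-means (defaults to the number
#'   of distinct labels).
#' @param eps_grid,min_samples_grid DBSCAN parameter grid.
#' @param methods clustering methods to run.
#' @param seed RNG seed for the k-means restarts.
#' @param all return the full grid instead of only the best row.
#' @return A tibble with columns `method`, `eps`, `min_samples`, `ari`,
#'   `nmi`, `mean_score`, ordered by score; only its best row unless
#'   `all = TRUE`.
#' @export
evaluate_embedding <- function(Z, labels = NULL, k_true = NULL,
                               eps_grid = seq(0.1, 2.0, by = 0.1),
                               min_samples_grid = c(5, 10, 20, 30),
                               methods = c("kmeans", "dbscan"),
                               seed = 0L, all = FALSE) {
  if (inherits(Z, "savae_fit")) {
    labels <- labels %||% Z$labels
    Z <- Z$latent
  }
  Z <- as.matrix(Z)
  stopifnot(nrow(Z) == length(labels))
  k_true <- k_true %||% length(unique(labels))
  rows <- list()
  if ("kmeans" %in% methods) {
    set.seed(seed)
    degenerate <- all(apply(Z, 2, function(col) diff(range(col)) == 0))
    km <- if (degenerate) rep(1L, nrow(Z))
          else kmeans(Z, centers = k_true, nstart = 10,
                      iter.max = 100)$cluster
    rows[[length(rows) + 1]] <- tibble::tibble(
      method = "kmeans", eps = NA_real_, min_samples = NA_real_,
      ari = ari(km, labels), nmi = nmi(km, labels))
  }
  if ("dbscan" %in% methods) {
    D <- as.matrix(dist(Z))
    for (ms in min_samples_grid) {
      for (e in eps_grid) {
        cl <- dbscan_cluster(Z, e, ms, D = D)
        rows[[length(rows) + 1]] <- tibble::tibble(
          method = "dbscan", eps = e, min_samples = ms,
          ari = ari(cl, labels), nmi = nmi(cl, labels))
      }
    }
  }
  out <- do.call(rbind, rows)
  out$mean_score <- (out$ari + out$nmi) / 2
  out <- out[order(-out$mean_score), ]
  if (all) out else out[1, ]
}
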