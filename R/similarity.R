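#' Exact k-nearest-neighbour search
#'
#' Brute-force Euclidean k-nearest neighbours, excluding self-matches.
#' Distances are computed in row chunks so memory stays bounded; the
#' search is exact at every problem size handled by this package.
#'
#' @param X numeric matrix (samples in rows) or a [labeled_matrix].
#' @param k number of neighbours per sample (must be `< nrow(X)`).
#' @param metric distance metric; only `"euclidean"` is implemented.
#' @param chunk rows per distance block.
#'
#' @return A `neighbor_graph`: list with `indices` (n x k integer matrix),
#'   `distances` (n x k, sorted nondecreasing within rows) and `metric`.
#' @export
knn_search <- function(X, k, metric = "euclidean", chunk = 1024L) {
  X <- lm_dense(X)
  metric <- match.arg(metric)
  if (!all(is.finite(X))) stop("X contains non-finite entries")
  n <- nrow(X)
  if (k >= n) stop("k must be smaller than the number of samples")
  if (k < 1) stop("k must be positive")

  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  sq <- rowSums(X^2)
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    d2 <- outer(sq[rows], sq, "+") - 2 * tcrossprod(X[rows, , drop = FALSE], X)
    d2[d2 < 0] <- 0
    for (r in seq_along(rows)) {
      i <- rows[r]
      v <- d2[r, ]
      v[i] <- Inf # exclude self by index, duplicates keep zero distance
      o <- order(v)[seq_len(k)]
      idx[i, ] <- o
      dst[i, ] <- sqrt(v[o])
    }
  }
  structure(list(indices = idx, distances = dst, metric = metric),
            class = "neighbor_graph")
}

#' Calibrate per-sample local scales for the fuzzy graph
#'
#' For each sample solves for the bandwidth `sigma_i` such that
#' `sum_j exp(-max(0, d_ij - rho_i) / sigma_i) = target`, where `rho_i`
#' is the distance to the nearest neighbour at strictly positive
#' distance. The solve is a vectorised bisection (absolute tolerance
#' `1e-5`, at most 64 iterations). Samples whose adjusted distances are
#' all zero (duplicates, or all neighbours equidistant at `rho_i`) have
#' a constant neighbour sum, so `sigma_i` is set to 1 and flagged.
#'
#' @param g a `neighbor_graph` from [knn_search()].
#' @param target calibration target; defaults to `log2(k)`, the smooth
#'   k-nearest-neighbour calibration.
#' @param tol,max_iter bisection controls.
#' @param verbose emit a message when degenerate samples are found.
#'
#' @return A `local_scales` list with `rho`, `sigma`, `degenerate`
#'   (logical flags) and `target`.
#' @export
calibrate_scales <- function(g, target = log2(ncol(g$indices)),
                             tol = 1e-5, max_iter = 64L, verbose = TRUE) {
  d <- g$distances
  n <- nrow(d)
  pos <- d > 0
  rho <- vapply(seq_len(n), function(i) {
    di <- d[i, pos[i, ]]
    if (length(di)) min(di) else 0
  }, numeric(1))

  adj <- pmax(d - rho, 0) # n x k
  degenerate <- rowSums(adj > 0) == 0

  # all 64 bisection iterations are always run: the interval collapses
  # far below `tol`, so downstream weights are reproducible to near
  # machine precision regardless of the stopping tolerance
  lo <- rep(0, n)
  hi <- rep(Inf, n)
  mid <- rep(1, n)
  active <- which(!degenerate)
  for (iter in seq_len(max_iter)) {
    if (!length(active)) break
    s <- rowSums(exp(-adj[active, , drop = FALSE] / mid[active]))
    over <- s > target
    hi[active[over]] <- mid[active[over]]
    lo[active[!over]] <- mid[active[!over]]
    grow <- !over & is.infinite(hi[active])
    mid[active[grow]] <- mid[active[grow]] * 2
    shrink <- !grow
    mid[active[shrink]] <- (lo[active[shrink]] + hi[active[shrink]]) / 2
  }
  sigma <- mid
  sigma[degenerate] <- 1
  if (any(degenerate) && verbose)
    savae_log("%d sample(s) with degenerate local scale (sigma set to 1)",
              sum(degenerate))
  structure(list(rho = rho, sigma = sigma, degenerate = degenerate,
                 target = target),
            class = "local_scales")
}

#' Directed local membership weights
#'
#' `w[i, j] = exp(-max(0, d(x_i, x_j) - rho_i) / sigma_i)` for `j` in
#' the neighbour list of `i`, 0 otherwise. The nearest neighbour at
#' positive distance always receives weight 1.
#'
#' @param g a `neighbor_graph`.
#' @param s a `local_scales` from [calibrate_scales()].
#' @return A sparse `dgCMatrix` of directed weights.
#' @export
local_weights <- function(g, s) {
  n <- nrow(g$indices)
  k <- ncol(g$indices)
  i <- rep(seq_len(n), each = k)
  j <- as.integer(t(g$indices))
  d <- as.numeric(t(g$distances))
  w <- exp(-pmax(0, d - s$rho[i]) / s$sigma[i])
  Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n))
}

#' Symmetrize directed weights into a fuzzy similarity graph
#'
#' Probabilistic t-conorm symmetrization:
#' `mu[i, j] = w[i, j] + w[j, i] - w[i, j] * w[j, i]`. The result is
#' exactly symmetric (bit level), zero on the diagonal, with stored
#' values in `(0, 1]`.
#'
#' @param w sparse directed weight matrix with values in `[0, 1]`.
#' @return A `fuzzy_graph`: list with `mu` (symmetric `dgCMatrix`) and `n`.
#' @export
symmetrize <- function(w) {
  if (any(w@x < 0) || any(w@x > 1)) stop("weights must lie in [0, 1]")
  tw <- Matrix::t(w)
  mu <- w + tw - w * tw
  mu <- Matrix::drop0(mu)
  Matrix::diag(mu) <- 0
  mu <- Matrix::drop0(mu)
  structure(list(mu = mu, n = nrow(mu)), class = "fuzzy_graph")
}

#' Build the full fuzzy similarity graph from data
#'
#' Convenience pipeline: [knn_search()] then [calibrate_scales()],
#' [local_weights()] and [symmetrize()]. Returns the graph along with
#' the intermediate quantities and a row-wise sampling cache used by
#' the positive-pair sampler.
#'
#' @inheritParams knn_search
#' @inheritParams calibrate_scales
#' @return A `fuzzy_graph` with additional fields `knn`, `scales`.
#' @export
fuzzy_graph <- function(X, k = 30, metric = "euclidean",
                        target = log2(k), verbose = TRUE) {
  g <- knn_search(X, k, metric)
  s <- calibrate_scales(g, target, verbose = verbose)
  fg <- symmetrize(local_weights(g, s))
  fg$knn <- g
  fg$scales <- s
  fg$csr <- fg_csr(fg)
  fg
}

#' @export
print.fuzzy_graph <- function(x, ...) {
  cat(sprintf("<fuzzy_graph> %d samples, %d undirected edges\n",
              x$n, length(x$mu@x) / 2))
  invisible(x)
}

# internal: row-wise CSR cache with cumulative weights for sampling.
# mu is symmetric so the columns of the dgCMatrix are its rows.
fg_csr <- function(fg) {
  mu <- fg$mu
  p <- mu@p
  list(row_ptr = p,
       col_idx = mu@i,
       cumprob = unlist(lapply(seq_len(fg$n), function(j) {
         if (p[j + 1L] > p[j]) cumsum(mu@x[(p[j] + 1L):p[j + 1L]])
         else numeric(0)
       }), use.names = FALSE))
}

# internal fast path: anchors (1-based), returns positive partner per
# anchor (0 for isolated anchors) plus the sampled edge's mu. Uses R RNG.
sample_pos_idx <- function(fg, anchors, per_anchor = 1L) {
  if (is.null(fg$csr)) fg$csr <- fg_csr(fg)
  cpp_sample_positive(fg$csr$row_ptr, fg$csr$col_idx, fg$csr$cumprob,
                      as.integer(anchors), as.integer(per_anchor))
}

#' Sample positive partners proportional to fuzzy similarity
#'
#' For each anchor draws `P` partners `j` with probability proportional
#' to `mu[i, j]`. Anchors with no positive-weight neighbour are skipped
#' (their count is reported).
#'
#' @param fg a `fuzzy_graph`.
#' @param anchors integer vector of anchor indices (1-based).
#' @param P partners per anchor.
#' @param verbose report skipped isolated anchors.
#' @return A tibble with columns `anchor`, `positive`.
#' @export
sample_positive_pairs <- function(fg, anchors, P = 1L, verbose = TRUE) {
  anchors <- as.integer(anchors)
  if (length(anchors) == 0)
    return(tibble::tibble(anchor = integer(0), positive = integer(0)))
  pos <- sample_pos_idx(fg, anchors, P)$idx
  anc <- rep(anchors, each = P)
  keep <- pos > 0L
  if (any(!keep) && verbose)
    savae_log("%d isolated anchor draw(s) skipped", sum(!keep))
  tibble::tibble(anchor = anc[keep], positive = pos[keep])
}

#' Uniform negative sampling from a candidate pool
#'
#' Draws uniformly with replacement. A draw that collides with the
#' anchor is redrawn once and then kept either way, so rare
#' self-collisions are tolerated rather than excluded outright.
#'
#' @param pool integer vector of candidate indices (the augmented
#'   minibatch).
#' @param count number of draws.
#' @param anchor optional anchor index used for the collision redraw.
#' @param verbose report kept self-collisions.
#' @return Integer vector of length `count`.
#' @export
sample_negatives <- function(pool, count, anchor = NULL, verbose = TRUE) {
  if (length(pool) == 0) stop("negative-sample pool is empty")
  count <- as.integer(count)
  if (count == 0L) return(integer(0))
  out <- pool[sample.int(length(pool), count, replace = TRUE)]
  if (!is.null(anchor)) {
    hit <- which(out == anchor)
    if (length(hit)) {
      out[hit] <- pool[sample.int(length(pool), length(hit), replace = TRUE)]
      kept <- sum(out[hit] == anchor)
      if (kept > 0 && verbose)
        savae_log("%d self-collision(s) kept after one resample", kept)
    }
  }
  out
}

#' Write / read a fuzzy graph as an edge-list TSV
#'
#' Three tab-separated columns `i`, `j`, `mu` with a one-line header and
#' 0-based indices; each undirected edge is stored once with `i < j`.
#'
#' @param fg a `fuzzy_graph`.
#' @param path file path.
#' @export
write_fuzzy_graph <- function(fg, path) {
  m <- Matrix::summary(Matrix::triu(fg$mu))
  df <- data.frame(i = m$i - 1L, j = m$j - 1L, mu = m$x)
  df <- df[order(df$i, df$j), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fuzzy_graph
#' @param n number of samples (defaults to `max(index) + 1`).
#' @export
read_fuzzy_graph <- function(path, n = NULL) {
  df <- read.delim(path)
  stopifnot(all(c("i", "j", "mu") %in% names(df)))
  n <- n %||% (max(df$i, df$j) + 1L)
  mu <- Matrix::sparseMatrix(i = c(df$i, df$j) + 1L, j = c(df$j, df$i) + 1L,
                             x = c(df$mu, df$mu), dims = c(n, n))
  structure(list(mu = mu, n = n), class = "fuzzy_graph")
}
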