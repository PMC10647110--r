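#' Non-parametric UMAP-style layout of a fuzzy graph
#'
#' Direct per-point embedding optimization of the fuzzy cross-entropy:
#' PCA initialization, then stochastic per-edge attract/repel updates
#' with a linearly decaying step size and clipped gradient
#' coefficients. Used by [visualize_2d()] to bring latent spaces with
#' more than two dimensions down to the plane; the trained models
#' themselves never depend on it.
#'
#' @param X data matrix, or a precomputed [fuzzy_graph()].
#' @param n_components embedding dimension.
#' @param k,min_dist,spread graph and curve parameters (visualization
#'   defaults `k = 15`, `min_dist = 0.1`).
#' @param epochs optimization epochs.
#' @param M negative samples per edge visit.
#' @param lr initial step size.
#' @param seed RNG seed.
#' @return Embedding matrix (n x `n_components`).
#' @export
umap_embed <- function(X, n_components = 2L, k = 15L, min_dist = 0.1,
                       spread = 1, epochs = 200L, M = 5L, lr = 1,
                       seed = 0L) {
  fg <- if (inherits(X, "fuzzy_graph")) X
        else fuzzy_graph(lm_dense(X), k = k, verbose = FALSE)
  curve <- fit_curve(min_dist, spread)
  a <- curve$a
  b <- curve$b
  n <- fg$n

  set.seed(seed)
  init <- if (inherits(X, "fuzzy_graph")) matrix(rnorm(n * n_components), n)
          else prcomp(lm_dense(X), rank. = n_components)$x
  Y <- init / max(abs(init)) * 10

  edges <- Matrix::summary(fg$mu)
  edges <- edges[edges$i != edges$j, ]
  w <- edges$x / max(edges$x)
  ei <- edges$i
  ej <- edges$j
  clip <- function(g) pmin(pmax(g, -4), 4)

  for (ep in seq_len(epochs)) {
    alpha <- lr * (1 - (ep - 1) / epochs)
    keep <- runif(length(w)) < w
    ii <- ei[keep]
    jj <- ej[keep]
    d2 <- rowSums((Y[ii, , drop = FALSE] - Y[jj, , drop = FALSE])^2)
    catt <- clip(-2 * a * b * pmax(d2, 1e-8)^(b - 1) /
                   (1 + a * d2^b))
    Ydelta <- (Y[ii, , drop = FALSE] - Y[jj, , drop = FALSE]) * catt
    upd <- rowsum(rbind(Ydelta, -Ydelta) * alpha, c(ii, jj))
    rows <- as.integer(rownames(upd))
    Y[rows, ] <- Y[rows, ] + upd
    for (neg in seq_len(M)) {
      kk <- sample.int(n, length(ii), replace = TRUE)
      d2n <- rowSums((Y[ii, , drop = FALSE] - Y[kk, , drop = FALSE])^2)
      crep <- clip(2 * b / ((0.001 + d2n) * (1 + a * d2n^b)))
      upd <- rowsum((Y[ii, , drop = FALSE] - Y[kk, , drop = FALSE]) *
                      crep * alpha, ii)
      rows <- as.integer(rownames(upd))
      Y[rows, ] <- Y[rows, ] + upd
    }
  }
  Y
}

#' Scatter plot of a 2-D embedding
#'
#' Plots a two-dimensional latent space directly; higher-dimensional
#' inputs are first reduced with [umap_embed()] (`k = 15`,
#' `min_dist = 0.1`, PCA initialization). When `path` is given the plot
#' is also written as an image file.
#'
#' @param Z latent matrix or `savae_fit`.
#' @param labels optional point labels for colouring.
#' @param path optional output image path (`.png`, `.pdf`, ...).
#' @param seed seed for the 2-D reduction when needed.
#' @param point_size scatter point size.
#' @return The `ggplot` object, invisibly when `path` is given.
#' @export
visualize_2d <- function(Z, labels = NULL, path = NULL, seed = 0L,
                         point_size = 0.6) {
  if (inherits(Z, "savae_fit")) {
    labels <- labels %||% Z$labels
    Z <- Z$latent
  }
  Z <- as.matrix(Z)
  coords <- if (ncol(Z) == 2) Z else umap_embed(Z, seed = seed)
  df <- tibble::tibble(dim1 = coords[, 1], dim2 = coords[, 2])
  p <- if (is.null(labels)) {
    ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2)) +
      ggplot2::geom_point(size = point_size, alpha = 0.7)
  } else {
    df$label <- factor(labels)
    ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                     colour = .data$label)) +
      ggplot2::geom_point(size = point_size, alpha = 0.7)
  }
  p <- p + ggplot2::labs(x = "dim 1", y = "dim 2") + ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 6, height = 5, dpi = 150)
    return(invisible(p))
  }
  p
}

#' @importFrom rlang .data
NULL

#' Autoplot method for fitted models
#'
#' The first two latent dimensions (or a 2-D reduction for deeper
#' latent spaces), coloured by the stored labels when present.
#'
#' @param object a `savae_fit`.
#' @param ... passed to [visualize_2d()].
#' @method autoplot savae_fit
#' @export
autoplot.savae_fit <- function(object, ...) {
  visualize_2d(object, ...)
}

#' Training-history plot
#'
#' Per-epoch reconstruction, KL and (when present) regularizer losses.
#'
#' @param fit a `savae_fit`.
#' @return A `ggplot` object.
#' @export
plot_history <- function(fit) {
  h <- fit$history
  long <- rbind(
    data.frame(epoch = h$epoch, loss = h$recon, term = "reconstruction"),
    data.frame(epoch = h$epoch, loss = h$kl, term = "KL"),
    if (any(is.finite(h$umap)))
      data.frame(epoch = h$epoch, loss = h$umap, term = "similarity")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$loss,
                                     colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
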