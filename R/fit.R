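#' Fit a plain variational autoencoder
#'
#' Minibatch Adam training of the negative ELBO with a single
#' reparametrized sample per row. Mainly a baseline for
#' [fit_savae()]; both share the same step engine.
#'
#' @param X sample-by-feature matrix or [labeled_matrix] (raw scale).
#' @param latent_dim,hidden_dim network sizes.
#' @param likelihood a [likelihood_spec()] or family name
#'   (`"gaussian"`, `"bernoulli"`, `"nb"`).
#' @param transform encoder input transform; defaults to `"log1p"` for
#'   counts and `"identity"` otherwise.
#' @param epochs,batch_size,lr training schedule (Adam, single thread).
#' @param seed RNG seed; training is reproducible given the seed.
#' @param verbose print per-epoch losses.
#' @return A `savae_fit` with the trained model, per-sample latent means
#'   and a per-epoch loss history.
#' @export
fit_vae <- function(X, latent_dim = 10L, hidden_dim = 512L,
                    likelihood = "gaussian", transform = NULL,
                    epochs = 200L, batch_size = 128L, lr = 1e-3,
                    seed = 0L, verbose = FALSE) {
  lm <- if (inherits(X, "labeled_matrix")) X else labeled_matrix(X)
  x <- lm_dense(lm)
  if (!inherits(likelihood, "likelihood_spec"))
    likelihood <- likelihood_spec(likelihood)
  transform <- transform %||%
    if (likelihood$family == "negative_binomial") "log1p" else "identity"

  set.seed(seed)
  model <- new_savae_model(ncol(x), latent_dim, hidden_dim, likelihood,
                           transform)
  opt <- adam_new(lr = lr)
  n <- nrow(x)
  hist <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- c(recon = 0, kl = 0)
    nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      batch <- ord[start:min(start + batch_size - 1L, n)]
      st <- vae_step_internal(model, x[batch, , drop = FALSE], NULL, opt)
      model <- st$model
      losses <- losses + c(st$recon, st$kl)
      nb <- nb + 1L
    }
    hist[[ep]] <- tibble::tibble(epoch = ep, recon = losses[[1]] / nb,
                                 kl = losses[[2]] / nb, umap = NA_real_)
    if (verbose)
      savae_log("epoch %d: recon %.4f kl %.4f", ep, losses[[1]] / nb,
                losses[[2]] / nb)
  }
  new_savae_fit(model, lm, history = do.call(rbind, hist), method = "vae",
                seed = seed,
                config = list(latent_dim = latent_dim,
                              hidden_dim = hidden_dim,
                              epochs = epochs, batch_size = batch_size,
                              lr = lr, lambda = 0, P = 0L))
}

#' Fit a similarity-assisted variational autoencoder
#'
#' Trains a VAE whose latent space is regularized by the UMAP-style
#' fuzzy cross-entropy computed on expected low-dimensional
#' similarities. The fuzzy similarity graph is built once on the
#' encoder-input representation (`log1p` counts, raw continuous data),
#' then every outer step performs one VAE update on an unpacked paired
#' minibatch and `update_ratio` regularizer updates on freshly sampled
#' positive/negative pairs. With `lambda = 0` and `P = 0` the procedure
#' is exactly plain VAE training under the same seed.
#'
#' @inheritParams fit_vae
#' @param k nearest-neighbour count of the fuzzy graph.
#' @param min_dist,spread low-dimensional similarity curve controls.
#' @param lambda regularizer weight.
#' @param update_ratio regularizer updates per VAE update (`I`).
#' @param P positives per anchor; `M` negatives per positive pair.
#' @param M see `P`.
#' @param graph optional precomputed [fuzzy_graph()] (used by the
#'   two-stage conditional variant, where the graph comes from
#'   covariate-adjusted embeddings).
#' @return A `savae_fit`.
#' @export
fit_savae <- function(X, latent_dim = 2L, hidden_dim = 512L,
                      likelihood = "gaussian", transform = NULL,
                      k = 30L, min_dist = 0, spread = 1,
                      lambda = 1e3, update_ratio = 5L, P = 1L, M = 5L,
                      epochs = 200L, batch_size = 128L, lr = 1e-3,
                      seed = 0L, graph = NULL, verbose = FALSE) {
  lm <- if (inherits(X, "labeled_matrix")) X else labeled_matrix(X)
  x <- lm_dense(lm)
  if (!inherits(likelihood, "likelihood_spec"))
    likelihood <- likelihood_spec(likelihood)
  transform <- transform %||%
    if (likelihood$family == "negative_binomial") "log1p" else "identity"

  plain <- (lambda == 0 && P == 0L)
  fg <- NULL
  curve <- NULL
  if (!plain) {
    fg <- graph %||%
      fuzzy_graph(transform_input(x, transform), k = k, verbose = verbose)
    if (is.null(fg$csr)) fg$csr <- fg_csr(fg)
    curve <- fit_curve(min_dist, spread)
  }

  set.seed(seed)
  model <- new_savae_model(ncol(x), latent_dim, hidden_dim, likelihood,
                           transform)
  opt <- adam_new(lr = lr)
  n <- nrow(x)
  hist <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- c(recon = 0, kl = 0, umap = 0)
    nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      batch <- ord[start:min(start + batch_size - 1L, n)]
      st <- savae_step(model, x, batch, fg, curve, opt,
                       lambda = lambda, I = update_ratio, P = P, M = M)
      model <- st$model
      losses <- losses + c(st$recon, st$kl, st$umap_loss)
      nb <- nb + 1L
    }
    hist[[ep]] <- tibble::tibble(epoch = ep, recon = losses[[1]] / nb,
                                 kl = losses[[2]] / nb,
                                 umap = losses[[3]] / nb)
    if (verbose)
      savae_log("epoch %d: recon %.4f kl %.4f umap %.4f", ep,
                losses[[1]] / nb, losses[[2]] / nb, losses[[3]] / nb)
  }
  new_savae_fit(model, lm, history = do.call(rbind, hist), method = "savae",
                seed = seed, graph = fg, curve = curve,
                config = list(latent_dim = latent_dim,
                              hidden_dim = hidden_dim, k = k,
                              min_dist = min_dist, spread = spread,
                              lambda = lambda, update_ratio = update_ratio,
                              P = P, M = M, epochs = epochs,
                              batch_size = batch_size, lr = lr))
}

#' Pick the regularizer weight by short probe trainings
#'
#' Implements the selection rule "the largest weight that still
#' decreases the VAE loss": every candidate `lambda` gets a short
#' probe run, and the largest candidate whose final VAE loss (recon +
#' KL) is below its starting loss is returned. Intended as a coarse
#' guide; the default `lambda = 1e3` is used throughout the package's
#' own experiments.
#'
#' @inheritParams fit_savae
#' @param grid candidate weights, tried in increasing order.
#' @param probe_epochs probe length per candidate.
#' @return The selected weight (scalar), with the probe summaries in
#'   attribute `"probes"`.
#' @export
select_lambda <- function(X, grid = c(1, 10, 100, 1e3, 1e4),
                          probe_epochs = 10L, latent_dim = 10L,
                          hidden_dim = 512L, likelihood = "gaussian",
                          k = 30L, seed = 0L, ...) {
  grid <- sort(grid)
  probes <- lapply(grid, function(lam) {
    f <- fit_savae(X, latent_dim = latent_dim, hidden_dim = hidden_dim,
                   likelihood = likelihood, k = k, lambda = lam,
                   epochs = probe_epochs, seed = seed, ...)
    h <- f$history
    tibble::tibble(lambda = lam,
                   first = h$recon[1] + h$kl[1],
                   last = h$recon[probe_epochs] + h$kl[probe_epochs])
  })
  probes <- do.call(rbind, probes)
  ok <- probes$last < probes$first
  sel <- if (any(ok)) max(probes$lambda[ok]) else min(grid)
  attr(sel, "probes") <- probes
  sel
}

# fitted-object container -------------------------------------------------

new_savae_fit <- function(model, lm, history, method, seed, config,
                          graph = NULL, curve = NULL, s = NULL,
                          extra = list()) {
  q <- encode(model, lm$values, s = s, train = FALSE)
  structure(c(list(model = model, latent = q$mean, latent_scale = q$scale,
                   sample_ids = lm$sample_ids, labels = lm$labels,
                   history = tibble::as_tibble(history), method = method,
                   seed = seed, config = config, graph = graph,
                   curve = curve, covariate_encoding = s),
              extra),
            class = "savae_fit")
}

#' @export
print.savae_fit <- function(x, ...) {
  cat(sprintf("<savae_fit:%s> %d samples -> %d latent dims, %d epochs\n",
              x$method, nrow(x$latent), ncol(x$latent),
              max(x$history$epoch)))
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final losses: recon %.4f kl %.4f%s\n", last$recon, last$kl,
              if (is.finite(last$umap)) sprintf(" umap %.4f", last$umap)
              else ""))
  invisible(x)
}

#' Reconstruct data through the decoder
#'
#' Decodes the posterior means of `x` (or the fitted data) back to
#' distribution parameters: the model's reconstruction.
#'
#' @param fit a `savae_fit`.
#' @param x optional new data on the raw scale; defaults to the fitted
#'   latent means.
#' @param s optional covariate encoding for conditional models.
#' @return Matrix of decoded distribution parameters.
#' @export
reconstruct <- function(fit, x = NULL, s = NULL) {
  if (is.null(x)) {
    z <- fit$latent
    s <- s %||% fit$covariate_encoding
  } else {
    q <- encode(fit$model, lm_dense(x), s = NULL, train = FALSE)
    z <- q$mean
  }
  decode(fit$model, z, s = s)
}
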