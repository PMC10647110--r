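#' Fit a covariate encoder
#'
#' Records, per covariate column, either the ordered categorical
#' vocabulary (factor levels, or sorted unique values) or the training
#' mean and standard deviation of a continuous covariate. Encoding is
#' one-hot blocks for categoricals concatenated with standardized
#' continuous values, so the encoding dimension is the total number of
#' levels plus the number of continuous covariates.
#'
#' @param covariates data frame of per-sample covariates (no missing
#'   values).
#' @param schema optional named character vector mapping column names to
#'   `"categorical"` or `"continuous"`; inferred from column types when
#'   omitted.
#' @return A `covariate_encoder`.
#' @export
fit_covariate_encoder <- function(covariates, schema = NULL) {
  covariates <- as.data.frame(covariates)
  if (anyNA(covariates)) stop("covariates contain missing values")
  cols <- lapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    type <- if (!is.null(schema) && nm %in% names(schema)) schema[[nm]]
            else if (is.numeric(v)) "continuous" else "categorical"
    if (type == "categorical") {
      levs <- if (is.factor(v)) levels(v) else sort(unique(as.character(v)))
      list(name = nm, type = "categorical", levels = levs)
    } else {
      s <- sd(v)
      constant <- !is.finite(s) || s == 0
      if (constant)
        warning("covariate '", nm, "' is constant; encoded as 0")
      list(name = nm, type = "continuous", mean = mean(v),
           sd = if (constant) 1 else s, constant = constant)
    }
  })
  dim <- sum(vapply(cols, function(cc)
    if (cc$type == "categorical") length(cc$levels) else 1L, integer(1)))
  structure(list(columns = cols, dim = dim), class = "covariate_encoder")
}

#' Encode covariates into a dense numeric matrix
#'
#' @param covariates data frame of per-sample covariates.
#' @param encoder a [fit_covariate_encoder()] result; fitted on the fly
#'   when omitted (the fitted encoder is attached as an attribute).
#' @return Numeric matrix (samples x encoding dimension) with the
#'   encoder in attribute `"encoder"`.
#' @export
encode_covariates <- function(covariates, encoder = NULL) {
  covariates <- as.data.frame(covariates)
  encoder <- encoder %||% fit_covariate_encoder(covariates)
  blocks <- lapply(encoder$columns, function(cc) {
    v <- covariates[[cc$name]]
    if (is.null(v)) stop("covariate column '", cc$name, "' is missing")
    if (cc$type == "categorical") {
      v <- as.character(v)
      bad <- setdiff(unique(v), cc$levels)
      if (length(bad))
        stop("unseen level(s) in covariate '", cc$name, "': ",
             paste(bad, collapse = ", "))
      m <- matrix(0, length(v), length(cc$levels),
                  dimnames = list(NULL, paste(cc$name, cc$levels, sep = ".")))
      m[cbind(seq_along(v), match(v, cc$levels))] <- 1
      m
    } else {
      val <- if (cc$constant) rep(0, length(v)) else (v - cc$mean) / cc$sd
      matrix(val, ncol = 1, dimnames = list(NULL, cc$name))
    }
  })
  out <- do.call(cbind, blocks)
  attr(out, "encoder") <- encoder
  out
}

#' One gradient step of CVAE training
#'
#' Single Adam update on the conditional negative ELBO
#' `-E_q log p(x | z, s) + KL(q || prior)` for a minibatch; the decoder
#' always receives the covariate sub-network output, the encoder only
#' under `conditional_encoder = TRUE`.
#'
#' @inheritParams vae_step
#' @param s covariate-encoding rows matching `x`.
#' @return List with updated `model` and scalar `recon`, `kl`, `loss`.
#' @export
cvae_step <- function(model, x, s, opt) {
  vae_step_internal(model, lm_dense(x), s, opt)
}

# reference covariate value s0: first categorical level, 0 for continuous
covariate_s0 <- function(encoder, n) {
  row <- unlist(lapply(encoder$columns, function(cc) {
    if (cc$type == "categorical") c(1, rep(0, length(cc$levels) - 1)) else 0
  }))
  matrix(row, n, encoder$dim, byrow = TRUE)
}

#' Fit a conditional variational autoencoder
#'
#' VAE training where the decoder receives the latent draw concatenated
#' with the output of a covariate sub-network (one fully connected
#' layer, ReLU, batch normalization, dropout). By default the encoder is
#' *not* conditioned on the covariates: `q(z | x)` absorbs the covariate
#' shift during training, which is what makes its means usable as
#' covariate-adjusted embeddings. Set `conditional_encoder = TRUE` for
#' the fully conditional form `q(z | x, s)`.
#'
#' @inheritParams fit_vae
#' @param covariates per-sample covariate data frame (or a
#'   [labeled_matrix] with covariates attached).
#' @param schema optional covariate schema, see
#'   [fit_covariate_encoder()].
#' @param cov_hidden covariate sub-network width.
#' @param conditional_encoder condition the encoder on covariates.
#' @return A `savae_fit` (method `"cvae"`).
#' @export
fit_cvae <- function(X, covariates = NULL, schema = NULL,
                     latent_dim = 10L, hidden_dim = 512L,
                     likelihood = "nb", transform = NULL,
                     cov_hidden = 128L, conditional_encoder = FALSE,
                     epochs = 200L, batch_size = 128L, lr = 1e-3,
                     seed = 0L, verbose = FALSE) {
  lm <- if (inherits(X, "labeled_matrix")) X else labeled_matrix(X)
  covariates <- covariates %||% lm$covariates
  if (is.null(covariates)) stop("covariates are required for a CVAE")
  x <- lm_dense(lm)
  if (!inherits(likelihood, "likelihood_spec"))
    likelihood <- likelihood_spec(likelihood)
  transform <- transform %||%
    if (likelihood$family == "negative_binomial") "log1p" else "identity"
  enc <- fit_covariate_encoder(covariates, schema)
  S <- encode_covariates(covariates, enc)

  set.seed(seed)
  model <- new_savae_model(ncol(x), latent_dim, hidden_dim, likelihood,
                           transform, cov_dim = enc$dim,
                           cov_hidden = cov_hidden,
                           conditional_encoder = conditional_encoder)
  opt <- adam_new(lr = lr)
  n <- nrow(x)
  hist <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- c(recon = 0, kl = 0)
    nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      batch <- ord[start:min(start + batch_size - 1L, n)]
      st <- vae_step_internal(model, x[batch, , drop = FALSE],
                              S[batch, , drop = FALSE], opt)
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
  new_savae_fit(model, lm, history = do.call(rbind, hist), method = "cvae",
                seed = seed, s = S,
                config = list(latent_dim = latent_dim,
                              hidden_dim = hidden_dim,
                              cov_hidden = cov_hidden,
                              conditional_encoder = conditional_encoder,
                              epochs = epochs, batch_size = batch_size,
                              lr = lr),
                extra = list(cov_encoder = enc))
}

#' Covariate-adjusted embeddings from a fitted conditional model
#'
#' In the default `"unconditional"` mode returns the means of
#' `q(z | x)` from the unconditionally trained encoder; identical
#' samples receive identical embeddings regardless of their covariates.
#' In `"s0"` mode (conditionally encoded models) all samples are pushed
#' through the encoder with the covariate fixed at the reference value
#' `s0` (first categorical level, zero for standardized continuous).
#'
#' @param fit a `savae_fit` from [fit_cvae()] or [fit_sacvae()].
#' @param x optional new data (raw scale); defaults to the fitted data's
#'   latent means.
#' @param mode `"unconditional"` or `"s0"`; must match how the encoder
#'   was trained.
#' @return Matrix of latent means.
#' @export
adjusted_embeddings <- function(fit, x = NULL,
                                mode = c("unconditional", "s0")) {
  mode <- match.arg(mode)
  conditional <- isTRUE(fit$config$conditional_encoder)
  if (mode == "unconditional" && conditional)
    stop("encoder was trained conditionally; use mode = \"s0\"")
  if (mode == "s0" && !conditional)
    stop("encoder was trained unconditionally; use mode = \"unconditional\"")
  if (is.null(x)) {
    if (!conditional) return(fit$latent)
    stop("fitted data are not stored; supply x for s0 mode")
  }
  x <- lm_dense(x)
  s <- if (conditional) covariate_s0(fit$cov_encoder, nrow(x)) else NULL
  encode(fit$model, x, s = s, train = FALSE)$mean
}

#' Two-stage similarity-assisted conditional VAE
#'
#' Stage 1 fits a plain CVAE; its covariate-adjusted embeddings (means
#' of `q(z | x)`) define a fuzzy similarity graph that is free of
#' covariate structure. Stage 2 trains a fresh CVAE with the fuzzy
#' cross-entropy regularizer computed against those stage-1 similarity
#' weights, with expected similarities from `q(z | x)`.
#'
#' @inheritParams fit_cvae
#' @inheritParams fit_savae
#' @param stage1_epochs stage-1 training length (defaults to `epochs`).
#' @return A `savae_fit` (method `"sacvae"`) with the stage-1 fit in
#'   `$stage1`.
#' @export
fit_sacvae <- function(X, covariates = NULL, schema = NULL,
                       latent_dim = 10L, hidden_dim = 512L,
                       likelihood = "nb", transform = NULL,
                       cov_hidden = 128L, conditional_encoder = FALSE,
                       k = 30L, min_dist = 0, spread = 1,
                       lambda = 1e3, update_ratio = 5L, P = 1L, M = 5L,
                       epochs = 200L, stage1_epochs = epochs,
                       batch_size = 128L, lr = 1e-3,
                       seed = 0L, verbose = FALSE) {
  lm <- if (inherits(X, "labeled_matrix")) X else labeled_matrix(X)
  covariates <- covariates %||% lm$covariates
  if (is.null(covariates)) stop("covariates are required for a saCVAE")
  x <- lm_dense(lm)
  if (!inherits(likelihood, "likelihood_spec"))
    likelihood <- likelihood_spec(likelihood)
  transform <- transform %||%
    if (likelihood$family == "negative_binomial") "log1p" else "identity"

  stage1 <- fit_cvae(lm, covariates, schema, latent_dim, hidden_dim,
                     likelihood, transform, cov_hidden,
                     conditional_encoder, stage1_epochs, batch_size, lr,
                     seed = seed, verbose = verbose)
  emb <- if (conditional_encoder)
    adjusted_embeddings(stage1, lm, mode = "s0")
  else stage1$latent
  fg <- fuzzy_graph(emb, k = k, verbose = verbose)
  curve <- fit_curve(min_dist, spread)

  enc <- stage1$cov_encoder
  S <- encode_covariates(covariates, enc)

  set.seed(seed + 1L)
  model <- new_savae_model(ncol(x), latent_dim, hidden_dim, likelihood,
                           transform, cov_dim = enc$dim,
                           cov_hidden = cov_hidden,
                           conditional_encoder = conditional_encoder)
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
                       lambda = lambda, I = update_ratio, P = P, M = M,
                       s = S)
      model <- st$model
      losses <- losses + c(st$recon, st$kl, st$umap_loss)
      nb <- nb + 1L
    }
    hist[[ep]] <- tibble::tibble(epoch = ep, recon = losses[[1]] / nb,
                                 kl = losses[[2]] / nb,
                                 umap = losses[[3]] / nb)
    if (verbose)
      savae_log("stage2 epoch %d: recon %.4f kl %.4f umap %.4f", ep,
                losses[[1]] / nb, losses[[2]] / nb, losses[[3]] / nb)
  }
  new_savae_fit(model, lm, history = do.call(rbind, hist),
                method = "sacvae", seed = seed, graph = fg, curve = curve,
                s = S,
                config = list(latent_dim = latent_dim,
                              hidden_dim = hidden_dim,
                              cov_hidden = cov_hidden,
                              conditional_encoder = conditional_encoder,
                              k = k, min_dist = min_dist, spread = spread,
                              lambda = lambda, update_ratio = update_ratio,
                              P = P, M = M, epochs = epochs,
                              stage1_epochs = stage1_epochs,
                              batch_size = batch_size, lr = lr),
                extra = list(cov_encoder = enc, stage1 = stage1))
}
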