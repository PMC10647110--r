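#' Construct an encoder/decoder model
#'
#' Encoder and decoder are multilayer perceptrons with three fully
#' connected layers and ReLU activations on the hidden ones. The encoder
#' outputs the mean and log-variance of the diagonal Gaussian posterior
#' `q(z | x)`; the decoder maps latent draws to the parameters of the
#' observation family. When a covariate encoding is supplied the decoder
#' input is the latent draw concatenated with the output of a covariate
#' sub-network (one fully connected layer with ReLU, batch normalization
#' and dropout); optionally the encoder can be conditioned the same way.
#'
#' @param input_dim number of features.
#' @param latent_dim latent dimension `J`.
#' @param hidden_dim hidden-layer width.
#' @param likelihood a [likelihood_spec()] or family name.
#' @param transform encoder input transform: `"identity"`, `"log1p"` or
#'   `"binarize"`. Count likelihoods require `"log1p"`.
#' @param cov_dim covariate-encoding dimension (0 for none).
#' @param cov_hidden width of the covariate sub-network.
#' @param conditional_encoder condition the encoder on covariates too
#'   (default `FALSE`: the encoder sees only `x`, which is what the
#'   covariate-shift correction relies on).
#' @param zero_final initialize final layers at zero (test fixture).
#' @return A `savae_model`.
#' @export
new_savae_model <- function(input_dim, latent_dim = 10L, hidden_dim = 512L,
                            likelihood = "gaussian",
                            transform = c("identity", "log1p", "binarize"),
                            cov_dim = 0L, cov_hidden = 128L,
                            conditional_encoder = FALSE,
                            zero_final = FALSE) {
  if (!inherits(likelihood, "likelihood_spec"))
    likelihood <- likelihood_spec(likelihood)
  transform <- match.arg(transform)
  if (likelihood$family == "negative_binomial" && transform != "log1p")
    stop("count likelihoods require the log1p input transform")
  enc_in <- input_dim + if (conditional_encoder && cov_dim > 0) cov_hidden else 0L
  dec_in <- latent_dim + if (cov_dim > 0) cov_hidden else 0L
  model <- list(
    enc = new_mlp(c(enc_in, hidden_dim, hidden_dim, 2L * latent_dim),
                  zero_final = zero_final),
    dec = new_mlp(c(dec_in, hidden_dim, hidden_dim, input_dim),
                  zero_final = zero_final),
    log_r = NULL,
    spec = likelihood,
    transform = transform,
    input_dim = input_dim, latent_dim = latent_dim, hidden_dim = hidden_dim,
    cov_dim = as.integer(cov_dim), cov_hidden = as.integer(cov_hidden),
    conditional_encoder = conditional_encoder,
    cov_dec = NULL, cov_enc = NULL
  )
  if (likelihood$family == "negative_binomial") {
    model$log_r <- if (is.null(likelihood$r)) rep(0, input_dim)
                   else log(rep(likelihood$r, length.out = input_dim))
  }
  if (cov_dim > 0) {
    model$cov_dec <- new_covnet(cov_dim, cov_hidden)
    if (conditional_encoder) model$cov_enc <- new_covnet(cov_dim, cov_hidden)
  }
  class(model) <- "savae_model"
  model
}

#' Encode samples into their variational posterior
#'
#' Applies the model's input transform and returns the mean and scale of
#' `q(z | x)` (and `q(z | x, s)` for a conditionally encoded model).
#' Deterministic given the parameters; batch normalization uses running
#' statistics (evaluation mode) unless `train = TRUE`.
#'
#' @param model a `savae_model`.
#' @param x sample-by-feature matrix (raw scale; the transform is
#'   applied internally) or [labeled_matrix].
#' @param s optional covariate-encoding matrix.
#' @param train forward in training mode (batch statistics, dropout).
#' @return List with `mean` and `scale` matrices (n x J).
#' @export
encode <- function(model, x, s = NULL, train = FALSE) {
  f <- enc_forward(model, lm_dense(x), s, train = train)
  list(mean = f$mean, scale = f$scale)
}

#' Decode latent points into distribution parameters
#'
#' Returns per-feature Bernoulli probabilities, Gaussian means, or
#' positive negative-binomial means depending on the model's likelihood.
#'
#' @param model a `savae_model`.
#' @param z latent matrix (n x J).
#' @param s optional covariate-encoding matrix (conditional models).
#' @return Matrix of distribution parameters.
#' @export
decode <- function(model, z, s = NULL) {
  f <- dec_forward(model, z, s, train = FALSE)
  switch(model$spec$family,
    bernoulli = 1 / (1 + exp(-f$out)),
    gaussian = f$out,
    negative_binomial = softplus(f$out) + 1e-6
  )
}

# --- internal forwards ---------------------------------------------------

enc_forward <- function(model, x, s = NULL, train = FALSE) {
  xt <- switch(model$transform, identity = x, log1p = log1p(x),
               transform_input(x, model$transform))
  cfwd <- NULL
  if (!is.null(model$cov_enc)) {
    if (is.null(s)) stop("conditionally encoded model needs covariates")
    cfwd <- covnet_fwd(model$cov_enc, s, train = train)
    xt <- cbind(xt, cfwd$out)
  }
  f <- mlp_fwd(model$enc, xt)
  J <- model$latent_dim
  logvar <- f$out[, J + seq_len(J), drop = FALSE]
  list(mean = f$out[, seq_len(J), drop = FALSE],
       logvar = logvar, scale = exp(0.5 * logvar),
       mlp = f, cov = cfwd)
}

dec_forward <- function(model, z, s = NULL, train = FALSE) {
  cfwd <- NULL
  if (!is.null(model$cov_dec)) {
    if (is.null(s)) stop("conditional model needs covariates for decoding")
    cfwd <- covnet_fwd(model$cov_dec, s, train = train)
    z <- cbind(z, cfwd$out)
  }
  f <- mlp_fwd(model$dec, z)
  list(out = f$out, mlp = f, cov = cfwd)
}

model_params <- function(model) {
  out <- c(mlp_params(model$enc, "enc"), mlp_params(model$dec, "dec"))
  if (!is.null(model$log_r) && model$spec$learn_r) out$log_r <- model$log_r
  if (!is.null(model$cov_dec)) out <- c(out, covnet_params(model$cov_dec, "cov_dec"))
  if (!is.null(model$cov_enc)) out <- c(out, covnet_params(model$cov_enc, "cov_enc"))
  out
}

model_set <- function(model, flat) {
  model$enc <- mlp_set(model$enc, flat, "enc")
  model$dec <- mlp_set(model$dec, flat, "dec")
  if (!is.null(model$log_r) && model$spec$learn_r) model$log_r <- flat$log_r
  if (!is.null(model$cov_dec)) model$cov_dec <- covnet_set(model$cov_dec, flat, "cov_dec")
  if (!is.null(model$cov_enc)) model$cov_enc <- covnet_set(model$cov_enc, flat, "cov_enc")
  model
}

# One gradient step on the (C)VAE loss -E_q log p(x|z[,s]) + KL(q||prior),
# expectation approximated with a single reparametrized draw. Returns the
# updated model and the per-sample mean loss components.
vae_step_internal <- function(model, x, s = NULL, opt) {
  n <- nrow(x)
  J <- model$latent_dim
  ef <- enc_forward(model, x, s, train = TRUE)
  eps <- matrix(rnorm(n * J), n, J)
  z <- ef$mean + ef$scale * eps
  df <- dec_forward(model, z, s, train = TRUE)
  if (!is.null(df$cov)) model$cov_dec <- df$cov$net # running BN stats
  if (!is.null(ef$cov)) model$cov_enc <- ef$cov$net

  xt_target <- if (model$spec$family == "bernoulli")
    transform_input(x, model$transform) else x
  res <- nll_and_grad(xt_target, df$out, model$spec, model$log_r)
  kl <- rowSums(0.5 * (ef$mean^2 + ef$scale^2 - 1) - log(ef$scale))

  dec_bwd <- mlp_bwd(model$dec, df$mlp, res$dout / n)
  grads <- mlp_grads(dec_bwd, "dec")
  dz <- dec_bwd$dX[, seq_len(J), drop = FALSE]
  if (!is.null(df$cov)) {
    dcov <- dec_bwd$dX[, J + seq_len(model$cov_hidden), drop = FALSE]
    grads <- c(grads, covnet_grads(covnet_bwd(model$cov_dec, df$cov, dcov),
                                   "cov_dec"))
  }
  if (!is.null(res$dlog_r) && model$spec$learn_r)
    grads$log_r <- res$dlog_r / n

  dmean <- ef$mean / n + dz
  dlogvar <- 0.5 * (ef$scale^2 - 1) / n + dz * eps * 0.5 * ef$scale
  enc_bwd <- mlp_bwd(model$enc, ef$mlp, cbind(dmean, dlogvar))
  grads <- c(grads, mlp_grads(enc_bwd, "enc"))
  if (!is.null(ef$cov)) {
    dcin <- enc_bwd$dX[, model$input_dim + seq_len(model$cov_hidden),
                       drop = FALSE]
    grads <- c(grads, covnet_grads(covnet_bwd(model$cov_enc, ef$cov, dcin),
                                   "cov_enc"))
  }

  params <- adam_step(opt, model_params(model), grads)
  model <- model_set(model, params)
  list(model = model,
       recon = mean(res$nll), kl = mean(kl),
       loss = mean(res$nll) + mean(kl))
}

#' One gradient step of plain VAE training
#'
#' Single Adam update on the negative ELBO of a minibatch, with the
#' expectation approximated by one reparametrized sample per row.
#'
#' @param model a `savae_model`.
#' @param x minibatch rows (raw scale).
#' @param opt an optimizer created by the fitting functions; exposed for
#'   step-level testing via [fit_vae()]'s `engine` internals.
#' @param s optional covariate encoding rows.
#' @return List with updated `model` and scalar `recon`, `kl`, `loss`.
#' @export
vae_step <- function(model, x, opt, s = NULL) {
  vae_step_internal(model, lm_dense(x), s, opt)
}

#' @export
print.savae_model <- function(x, ...) {
  cat(sprintf("<savae_model> %d features -> %d latent (hidden %d, %s%s)\n",
              x$input_dim, x$latent_dim, x$hidden_dim, x$spec$family,
              if (x$cov_dim > 0) ", conditional" else ""))
  invisible(x)
}
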