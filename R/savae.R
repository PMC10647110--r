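#' Expected low-dimensional similarity between two posteriors
#'
#' Monte-Carlo estimate of
#' `E_{q(z|x_i)} E_{q(z'|x_j)} 1 / (1 + a ||z - z'||^(2b))` using
#' `n_draws` reparametrized draws per posterior (a single draw during
#' training). The estimate is clamped to `[1e-6, 1 - 1e-6]` before any
#' logarithm.
#'
#' @param qi,qj posteriors: lists with `mean` and `scale` vectors (or
#'   single-row matrices).
#' @param curve a [fit_curve()] result.
#' @param n_draws Monte-Carlo sample size.
#' @return Scalar estimate of the expected similarity.
#' @export
expected_similarity <- function(qi, qj, curve, n_draws = 1L) {
  J <- length(qi$mean)
  zi <- matrix(qi$mean, n_draws, J, byrow = TRUE) +
    matrix(qi$scale, n_draws, J, byrow = TRUE) * matrix(rnorm(n_draws * J), n_draws)
  zj <- matrix(qj$mean, n_draws, J, byrow = TRUE) +
    matrix(qj$scale, n_draws, J, byrow = TRUE) * matrix(rnorm(n_draws * J), n_draws)
  nu <- mean(low_dim_similarity(zi, zj, curve))
  min(max(nu, 1e-6), 1 - 1e-6)
}

#' Build a paired minibatch of anchors, positives and negatives
#'
#' For every anchor in `batch`, draws `P` positive partners proportional
#' to the fuzzy similarities and `M` negatives per positive pair,
#' uniformly with replacement from the augmented minibatch (anchors plus
#' sampled positives; a draw colliding with its anchor is redrawn once).
#' The `unpacked` element interleaves anchors with their positives,
#' `x_i, x_i^1, x_i, x_i^2, ...`, and is the minibatch used for the VAE
#' term. Isolated anchors (no positive-weight neighbour) contribute no
#' pair.
#'
#' @param batch integer vector of anchor indices.
#' @param fg a [fuzzy_graph()].
#' @param P positives per anchor.
#' @param M negatives per positive pair.
#' @return A `paired_batch`: list with `anchors`, `positives`, `mu`,
#'   `negatives` (`n_pairs` x `M` matrix) and `unpacked`.
#' @export
build_paired_minibatch <- function(batch, fg, P = 1L, M = 5L) {
  batch <- as.integer(batch)
  if (P == 0L)
    return(structure(list(anchors = integer(0), positives = integer(0),
                          mu = numeric(0),
                          negatives = matrix(integer(0), 0, M),
                          unpacked = batch),
                     class = "paired_batch"))
  samp <- sample_pos_idx(fg, batch, P)
  anc <- rep(batch, each = P)
  keep <- samp$idx > 0L
  anchors <- anc[keep]
  positives <- samp$idx[keep]
  mu <- samp$mu[keep]

  # interleave x_i with each of its positives
  unpacked <- as.integer(rbind(anchors, positives))

  m <- length(anchors)
  negatives <- matrix(integer(0), 0, M)
  if (m > 0 && M > 0) {
    pool <- unpacked
    draws <- matrix(pool[sample.int(length(pool), m * M, replace = TRUE)], m, M)
    hit <- which(draws == anchors) # recycles anchors over columns
    if (length(hit))
      draws[hit] <- pool[sample.int(length(pool), length(hit), replace = TRUE)]
    negatives <- draws
  }
  structure(list(anchors = anchors, positives = positives, mu = mu,
                 negatives = negatives, unpacked = unpacked),
            class = "paired_batch")
}

#' Negative-sampling estimate of the fuzzy cross-entropy regularizer
#'
#' Computes `-sum_pairs log(nu_ij) - sum_negatives log(1 - nu_in)` over
#' a paired minibatch: the negative-sampling estimate of the fuzzy
#' cross-entropy double sum, in which the attractive `mu_ij` weight is
#' absorbed by drawing positive pairs proportional to `mu` and
#' negatives carry target similarity 0 (their `1 - mu` factor is taken
#' as 1). `nu` values are single-draw expected similarities, clamped
#' to `[1e-6, 1 - 1e-6]`.
#'
#' @param pb a [build_paired_minibatch()] result.
#' @param posteriors list with `mean` and `scale` matrices covering all
#'   sample indices referenced by `pb`.
#' @param curve a [fit_curve()] result.
#' @return Scalar regularizer value (nonnegative up to clamping).
#' @export
umap_regularizer <- function(pb, posteriors, curve) {
  if (length(pb$anchors) == 0 && length(pb$negatives) == 0) return(0)
  u <- sort(unique(c(pb$anchors, pb$positives, as.integer(pb$negatives))))
  eps <- matrix(rnorm(length(u) * ncol(posteriors$mean)), length(u))
  z <- posteriors$mean[u, , drop = FALSE] +
    posteriors$scale[u, , drop = FALSE] * eps
  ia <- match(pb$anchors, u)
  ip <- match(pb$positives, u)
  d2 <- rowSums((z[ia, , drop = FALSE] - z[ip, , drop = FALSE])^2)
  nu <- clamp01(1 / (1 + curve$a * d2^curve$b))
  val <- -sum(log(nu))
  if (length(pb$negatives)) {
    M <- ncol(pb$negatives)
    ian <- rep(ia, times = M)
    inn <- match(as.integer(pb$negatives), u)
    d2n <- rowSums((z[ian, , drop = FALSE] - z[inn, , drop = FALSE])^2)
    nun <- clamp01(1 / (1 + curve$a * d2n^curve$b))
    val <- val - sum(log1p(-nun))
  }
  val
}

clamp01 <- function(x, eps = 1e-6) pmin(pmax(x, eps), 1 - eps)

# per-dimension clipping of pairwise embedding forces, as in reference
# edge-wise fuzzy cross-entropy optimizers
clip4 <- function(g) {
  g[g > 4] <- 4
  g[g < -4] <- -4
  g
}

# internal: one gradient update of lambda * regularizer w.r.t. encoder
# parameters, on freshly sampled pairs for the given anchors.
# Gradients flow through the single reparametrized draw of every
# involved sample. Squared distances are floored (1e-8 attractive,
# 1e-3 additive repulsive) so the power-law gradients stay finite when
# two draws coincide.
umap_update <- function(model, X, S, anchors, fg, curve, lambda, P, M, opt) {
  samp <- sample_pos_idx(fg, anchors, P)
  anc <- rep(anchors, each = P)
  keep <- samp$idx > 0L
  a_i <- anc[keep]
  p_i <- samp$idx[keep]
  mu <- samp$mu[keep]
  m <- length(a_i)
  if (m == 0) {
    opt$t <- opt$t + 1L
    return(list(model = model, value = 0))
  }
  pool <- as.integer(rbind(a_i, p_i))
  negs <- matrix(pool[sample.int(length(pool), m * M, replace = TRUE)], m, M)
  hit <- which(negs == a_i)
  if (length(hit))
    negs[hit] <- pool[sample.int(length(pool), length(hit), replace = TRUE)]

  u <- sort(unique(c(a_i, p_i, as.integer(negs))))
  ef <- enc_forward(model, X[u, , drop = FALSE],
                    if (is.null(S)) NULL else S[u, , drop = FALSE],
                    train = TRUE)
  if (!is.null(ef$cov)) model$cov_enc <- ef$cov$net
  J <- model$latent_dim
  eps <- matrix(rnorm(length(u) * J), length(u), J)
  z <- ef$mean + ef$scale * eps

  ia <- match(a_i, u)
  ip <- match(p_i, u)
  za <- z[ia, , drop = FALSE]
  zp <- z[ip, , drop = FALSE]
  d2 <- rowSums((za - zp)^2)
  nu <- clamp01(1 / (1 + curve$a * d2^curve$b))
  # positives are sampled proportional to mu, which absorbs the mu_ij
  # factor of the double sum; each visited pair contributes -log(nu)
  value <- -sum(log(nu))
  catt <- curve$a * curve$b * pmax(d2, 1e-8)^(curve$b - 1) * nu
  gpos <- clip4(2 * (za - zp) * catt)

  ian <- rep(ia, times = M)
  inn <- match(as.integer(negs), u)
  zan <- z[ian, , drop = FALSE]
  zn <- z[inn, , drop = FALSE]
  d2n <- rowSums((zan - zn)^2)
  nun <- clamp01(1 / (1 + curve$a * d2n^curve$b))
  value <- value - sum(log1p(-nun))
  cneg <- -curve$b * nun / (d2n + 1e-3)
  gneg <- clip4(2 * (zan - zn) * cneg)

  idx <- c(ia, ip, ian, inn)
  contrib <- rbind(gpos, -gpos, gneg, -gneg)
  agg <- rowsum(contrib, idx)
  dz <- matrix(0, length(u), J)
  dz[as.integer(rownames(agg)), ] <- agg
  dz <- lambda * dz

  dmean <- dz
  dlogvar <- dz * eps * 0.5 * ef$scale
  enc_bwd <- mlp_bwd(model$enc, ef$mlp, cbind(dmean, dlogvar))
  grads <- mlp_grads(enc_bwd, "enc")
  if (!is.null(ef$cov)) {
    dcin <- enc_bwd$dX[, model$input_dim + seq_len(model$cov_hidden),
                       drop = FALSE]
    grads <- c(grads, covnet_grads(covnet_bwd(model$cov_enc, ef$cov, dcin),
                                   "cov_enc"))
  }
  params <- adam_step(opt, model_params(model), grads)
  model <- model_set(model, params)
  list(model = model, value = value)
}

#' One combined saVAE training step
#'
#' A single outer step: one gradient update of the VAE loss on the
#' unpacked paired minibatch, followed by `I` gradient updates of
#' `lambda` times the fuzzy cross-entropy regularizer on freshly
#' sampled pairs for the same anchors. The regularizer only touches
#' encoder parameters; both objectives share one Adam instance. With
#' `lambda = 0` and `P = 0` the step reduces exactly to [vae_step()].
#'
#' @param model a `savae_model`.
#' @param X full data matrix (raw scale).
#' @param batch anchor indices for this step.
#' @param fg a [fuzzy_graph()].
#' @param curve a [fit_curve()] result.
#' @param opt shared optimizer.
#' @param lambda regularizer weight.
#' @param I regularizer updates per VAE update.
#' @param P,M sampler sizes.
#' @param s optional covariate-encoding matrix (full data).
#' @return List with updated `model`, `vae_loss` (recon + KL) and
#'   `umap_loss` (last inner value).
#' @export
savae_step <- function(model, X, batch, fg, curve, opt,
                       lambda = 1e3, I = 5L, P = 1L, M = 5L, s = NULL) {
  if (lambda == 0 && P == 0L) {
    st <- vae_step_internal(model, X[batch, , drop = FALSE],
                            if (is.null(s)) NULL else s[batch, , drop = FALSE],
                            opt)
    return(list(model = st$model, vae_loss = st$loss, recon = st$recon,
                kl = st$kl, umap_loss = 0))
  }
  pb <- build_paired_minibatch(batch, fg, P, M)
  rows <- if (length(pb$unpacked)) pb$unpacked else batch
  st <- vae_step_internal(model, X[rows, , drop = FALSE],
                          if (is.null(s)) NULL else s[rows, , drop = FALSE],
                          opt)
  model <- st$model
  uval <- 0
  for (it in seq_len(I)) {
    up <- umap_update(model, X, s, batch, fg, curve, lambda, P, M, opt)
    model <- up$model
    uval <- up$value
  }
  list(model = model, vae_loss = st$loss, recon = st$recon, kl = st$kl,
       umap_loss = uval)
}
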