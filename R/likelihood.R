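#' Decoder likelihood specification
#'
#' The decoder family used for the observation model: `bernoulli` for
#' binarized data, `gaussian` (unit variance) for continuous data, and
#' `negative_binomial` (mean--dispersion form) for counts. The NB
#' dispersion `r` is one free positive parameter per feature, learned
#' jointly with the network weights by default; a fixed `r` can be
#' supplied instead.
#'
#' @param family one of `"bernoulli"`, `"gaussian"`, `"negative_binomial"`
#'   (alias `"nb"`).
#' @param r optional positive per-feature dispersion vector (NB only).
#'   When supplied with `learn_r = FALSE` it is held fixed.
#' @param learn_r should the dispersion be optimized?
#' @return A `likelihood_spec`.
#' @export
likelihood_spec <- function(family = c("negative_binomial", "nb",
                                       "gaussian", "bernoulli"),
                            r = NULL, learn_r = is.null(r)) {
  family <- match.arg(family)
  if (family == "nb") family <- "negative_binomial"
  if (!is.null(r) && any(r <= 0)) stop("NB dispersion r must be positive")
  structure(list(family = family, r = r, learn_r = learn_r),
            class = "likelihood_spec")
}

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Exact log-likelihood of a decoder family
#'
#' Per-sample log density/mass summed over features. The negative
#' binomial uses the mean--dispersion parameterization
#' `log P(x) = lgamma(x + r) - lgamma(r) - lgamma(x + 1) +
#'  r log(r / (r + m)) + x log(m / (r + m))`
#' with `m` the decoded mean. The Gaussian has unit variance and keeps
#' the `-log(2 pi)/2` constant so losses are comparable across runs.
#'
#' @param x data matrix (samples in rows), in the family's support.
#' @param params decoded distribution parameters: probabilities
#'   (bernoulli), means (gaussian), or positive means (NB).
#' @param spec a [likelihood_spec()]; for the NB, `spec$r` must hold the
#'   per-feature dispersion in use.
#' @return Numeric vector of per-sample log-likelihoods.
#' @export
log_likelihood <- function(x, params, spec) {
  x <- as.matrix(x)
  params <- as.matrix(params)
  stopifnot(all(dim(x) == dim(params)))
  switch(spec$family,
    bernoulli = {
      if (any(x != 0 & x != 1)) stop("bernoulli data must be binary")
      rowSums(x * log(params) + (1 - x) * log1p(-params))
    },
    gaussian = {
      rowSums(-0.5 * (x - params)^2) - 0.5 * ncol(x) * log(2 * pi)
    },
    negative_binomial = {
      if (any(x < 0) || any(x != round(x)))
        stop("negative binomial data must be nonnegative integers")
      r <- rep(spec$r, length.out = ncol(x))
      rmat <- rep(r, each = nrow(x))
      m <- params
      rowSums(lgamma(x + rmat) - lgamma(rmat) - lgamma(x + 1) +
                rmat * log(rmat / (rmat + m)) + x * log(m / (rmat + m)))
    }
  )
}

#' Closed-form KL divergence to the standard normal prior
#'
#' `KL(q || N(0, I)) = -1/2 sum_j (1 + log sigma_j^2 - mu_j^2 - sigma_j^2)`,
#' nonnegative and zero exactly when `mean = 0`, `scale = 1`.
#'
#' @param mean matrix (or vector) of posterior means.
#' @param scale matrix (or vector) of positive posterior scales.
#' @return Per-sample nonnegative KL values.
#' @export
kl_standard_normal <- function(mean, scale) {
  if (is.null(dim(mean))) {
    mean <- matrix(mean, 1)
    scale <- matrix(scale, 1)
  }
  stopifnot(all(scale > 0))
  rowSums(0.5 * (mean^2 + scale^2 - 1) - log(scale))
}

#' Reparametrized sampling from the variational posterior
#'
#' `z = mean + scale * eps` elementwise, with `eps` standard normal.
#'
#' @param q list with `mean` and `scale` matrices (a posterior batch).
#' @param eps standard-normal draws of matching shape; drawn from the
#'   session RNG when omitted.
#' @return Matrix of latent draws.
#' @export
reparameterize <- function(q, eps = NULL) {
  if (is.null(eps))
    eps <- matrix(rnorm(length(q$mean)), nrow(q$mean), ncol(q$mean))
  stopifnot(all(dim(eps) == dim(q$mean)))
  q$mean + q$scale * eps
}

# internal: per-family negative log-likelihood and gradient w.r.t. the
# decoder's linear output `o`. Natural-parameter maps:
#   bernoulli  p = sigmoid(o)
#   gaussian   m = o
#   nb         m = softplus(o) + 1e-6
nll_and_grad <- function(x, o, spec, log_r = NULL) {
  switch(spec$family,
    bernoulli = {
      p <- 1 / (1 + exp(-o))
      nll <- -rowSums(x * log(p) + (1 - x) * log1p(-p))
      list(nll = nll, dout = p - x, dlog_r = NULL, params = p)
    },
    gaussian = {
      nll <- rowSums(0.5 * (x - o)^2) + 0.5 * ncol(x) * log(2 * pi)
      list(nll = nll, dout = o - x, dlog_r = NULL, params = o)
    },
    negative_binomial = {
      n <- nrow(x)
      r <- exp(log_r)
      rmat <- rep(r, each = n)
      m <- softplus(o) + 1e-6
      nll <- -rowSums(lgamma(x + rmat) - lgamma(rmat) - lgamma(x + 1) +
                        rmat * log(rmat / (rmat + m)) +
                        x * log(m / (rmat + m)))
      dm <- (rmat + x) / (rmat + m) - x / m
      dout <- dm / (1 + exp(-o)) # chain through softplus
      dr <- -(digamma(x + rmat) - digamma(rmat) + log(rmat / (rmat + m)) +
                1 - (rmat + x) / (rmat + m))
      dlog_r <- colSums(dr) * r
      list(nll = nll, dout = dout, dlog_r = dlog_r, params = m)
    }
  )
}
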