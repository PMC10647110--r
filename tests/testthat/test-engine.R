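# Gradient checks of the hand-written backprop against central finite
# differences, on tiny networks where the losses are smooth.

vae_loss_from_params <- function(model, flat, x, s, eps) {
  model <- savae:::model_set(model, flat)
  ef <- savae:::enc_forward(model, x, s, train = TRUE)
  z <- ef$mean + ef$scale * eps
  df <- savae:::dec_forward(model, z, s, train = TRUE)
  res <- savae:::nll_and_grad(x, df$out, model$spec, model$log_r)
  kl <- rowSums(0.5 * (ef$mean^2 + ef$scale^2 - 1) - log(ef$scale))
  mean(res$nll) + mean(kl)
}

test_that("VAE gradients match finite differences for every family", {
  set.seed(101)
  n <- 6
  for (family in c("gaussian", "bernoulli", "negative_binomial")) {
    transform <- if (family == "negative_binomial") "log1p" else "identity"
    model <- new_savae_model(5, latent_dim = 2, hidden_dim = 4,
                             likelihood = family, transform = transform)
    x <- switch(family,
      gaussian = matrix(rnorm(n * 5), n),
      bernoulli = matrix(rbinom(n * 5, 1, 0.4), n),
      negative_binomial = matrix(rpois(n * 5, 3), n))
    eps <- matrix(rnorm(n * 2), n)

    # analytic grads via a zero-lr optimizer probe
    opt <- savae:::adam_new(lr = 0)
    ef <- savae:::enc_forward(model, x, NULL, train = TRUE)
    z <- ef$mean + ef$scale * eps
    df <- savae:::dec_forward(model, z, NULL, train = TRUE)
    res <- savae:::nll_and_grad(x, df$out, model$spec, model$log_r)
    dec_bwd <- savae:::mlp_bwd(model$dec, df$mlp, res$dout / n)
    grads <- savae:::mlp_grads(dec_bwd, "dec")
    dz <- dec_bwd$dX
    if (!is.null(res$dlog_r)) grads$log_r <- res$dlog_r / n
    dmean <- ef$mean / n + dz
    dlogvar <- 0.5 * (ef$scale^2 - 1) / n + dz * eps * 0.5 * ef$scale
    enc_bwd <- savae:::mlp_bwd(model$enc, ef$mlp, cbind(dmean, dlogvar))
    grads <- c(grads, savae:::mlp_grads(enc_bwd, "enc"))

    flat <- savae:::model_params(model)
    num <- numeric_grad(function(p)
      vae_loss_from_params(model, p, x, NULL, eps), flat)
    expect_lt(max_rel_err(grads[names(flat)], num), 1e-5)
  }
})

umap_loss_from_params <- function(model, flat, X, pairs, negs, mu, curve,
                                  eps, u) {
  model <- savae:::model_set(model, flat)
  ef <- savae:::enc_forward(model, X[u, , drop = FALSE], NULL, train = TRUE)
  z <- ef$mean + ef$scale * eps
  ia <- match(pairs[, 1], u)
  ip <- match(pairs[, 2], u)
  d2 <- rowSums((z[ia, , drop = FALSE] - z[ip, , drop = FALSE])^2)
  nu <- 1 / (1 + curve$a * d2^curve$b)
  val <- -sum(mu * log(nu))
  ian <- rep(ia, times = ncol(negs))
  inn <- match(as.integer(negs), u)
  d2n <- rowSums((z[ian, , drop = FALSE] - z[inn, , drop = FALSE])^2)
  nun <- 1 / (1 + curve$a * (d2n + 1e-3 * 0)^curve$b)
  val - sum(log1p(-nun))
}

test_that("regularizer encoder gradients match finite differences", {
  # smooth regime: distances far from zero so the stabilizer floors are
  # inactive and the analytic gradient is exact
  set.seed(33)
  model <- new_savae_model(3, latent_dim = 2, hidden_dim = 4,
                           likelihood = "gaussian")
  X <- matrix(rnorm(8 * 3, sd = 3), 8)
  pairs <- cbind(c(1L, 3L), c(2L, 5L))
  negs <- matrix(c(6L, 7L, 8L, 4L), 2)
  mu <- c(0.9, 0.4)
  curve <- list(a = 1.2, b = 1.0) # b = 1 keeps d2^(b-1) exactly 1
  u <- 1:8
  eps <- matrix(rnorm(16), 8)

  flat <- savae:::model_params(model)
  # analytic gradient reproduced from the training path
  ef <- savae:::enc_forward(model, X, NULL, train = TRUE)
  z <- ef$mean + ef$scale * eps
  ia <- match(pairs[, 1], u); ip <- match(pairs[, 2], u)
  d2 <- rowSums((z[ia, ] - z[ip, ])^2)
  nu <- 1 / (1 + curve$a * d2^curve$b)
  catt <- mu * curve$a * curve$b * pmax(d2, 1e-8)^(curve$b - 1) * nu
  gpos <- 2 * (z[ia, ] - z[ip, ]) * catt
  ian <- rep(ia, times = 2); inn <- match(as.integer(negs), u)
  d2n <- rowSums((z[ian, ] - z[inn, ])^2)
  nun <- 1 / (1 + curve$a * d2n^curve$b)
  cneg <- -curve$b * nun / (d2n + 1e-3 * 0)
  gneg <- 2 * (z[ian, ] - z[inn, ]) * cneg
  agg <- rowsum(rbind(gpos, -gpos, gneg, -gneg), c(ia, ip, ian, inn))
  dz <- matrix(0, 8, 2)
  dz[as.integer(rownames(agg)), ] <- agg
  enc_bwd <- savae:::mlp_bwd(model$enc, ef$mlp,
                             cbind(dz, dz * eps * 0.5 * ef$scale))
  grads <- savae:::mlp_grads(enc_bwd, "enc")

  enc_keys <- grep("^enc", names(flat), value = TRUE)
  num <- numeric_grad(function(p)
    umap_loss_from_params(model, p, X, pairs, negs, mu, curve, eps, u),
    flat)
  expect_lt(max_rel_err(grads[enc_keys], num[enc_keys]), 1e-5)
})

test_that("covariate sub-network gradients match finite differences", {
  set.seed(55)
  net <- savae:::new_covnet(3, d_hidden = 5, p_drop = 0)
  S <- matrix(rnorm(7 * 3), 7)
  w <- matrix(rnorm(5), 5, 1) # project output to a scalar loss
  loss_fn <- function(nn) {
    f <- savae:::covnet_fwd(nn, S, train = TRUE)
    sum((f$out %*% w)^2)
  }
  f <- savae:::covnet_fwd(net, S, train = TRUE)
  dout <- 2 * (f$out %*% w) %*% t(w)
  g <- savae:::covnet_bwd(net, f, dout)
  flat <- savae:::covnet_params(net, "c")
  num <- numeric_grad(function(p)
    loss_fn(savae:::covnet_set(net, p, "c")), flat)
  ana <- savae:::covnet_grads(g, "c")
  expect_lt(max_rel_err(ana[names(flat)], num), 1e-4)
})

test_that("zero-initialized heads give the neutral posterior and outputs", {
  model <- new_savae_model(4, latent_dim = 3, hidden_dim = 6,
                           likelihood = "bernoulli", zero_final = TRUE)
  x <- matrix(rnorm(10 * 4), 10)
  q <- encode(model, x)
  expect_true(all(q$mean == 0))
  expect_true(all(q$scale == 1))
  p <- decode(model, matrix(rnorm(10 * 3), 10))
  expect_true(all(p == 0.5)) # sigmoid(0)
})

test_that("encoding is deterministic and respects the input transform", {
  model <- new_savae_model(4, latent_dim = 2, hidden_dim = 6,
                           likelihood = "gaussian")
  x <- matrix(abs(rnorm(6 * 4)), 6)
  q1 <- encode(model, x)
  q2 <- encode(model, x)
  expect_identical(q1, q2)
  # identical rows -> identical posteriors
  xx <- rbind(x[1, ], x[1, ])
  q <- encode(model, xx)
  expect_equal(q$mean[1, ], q$mean[2, ])
  # log1p(0) = 0: zero vector encodes identically under both transforms
  m2 <- new_savae_model(4, latent_dim = 2, hidden_dim = 6,
                        likelihood = "gaussian", transform = "log1p")
  m2$enc <- model$enc
  z0 <- matrix(0, 1, 4)
  expect_equal(encode(model, z0)$mean, encode(m2, z0)$mean)
})

test_that("NB decoder means are strictly positive", {
  model <- new_savae_model(5, latent_dim = 2, hidden_dim = 6,
                           likelihood = "nb", transform = "log1p")
  m <- decode(model, matrix(rnorm(20), 10))
  expect_true(all(m > 0))
})

test_that("the KL term of the VAE loss equals the closed form over the batch", {
  set.seed(12)
  model <- new_savae_model(4, latent_dim = 2, hidden_dim = 6,
                           likelihood = "gaussian")
  x <- matrix(rnorm(5 * 4), 5)
  q <- encode(model, x)
  expected_kl <- mean(kl_standard_normal(q$mean, q$scale))
  opt <- savae:::adam_new(lr = 1e-3)
  st <- vae_step(model, x, opt)
  expect_equal(st$kl, expected_kl)
})

test_that("Adam with zero learning rate leaves parameters unchanged", {
  set.seed(6)
  model <- new_savae_model(3, latent_dim = 2, hidden_dim = 4,
                           likelihood = "gaussian")
  opt <- savae:::adam_new(lr = 0)
  before <- savae:::model_params(model)
  st <- vae_step(model, matrix(rnorm(12), 4), opt)
  expect_identical(savae:::model_params(st$model), before)
})
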