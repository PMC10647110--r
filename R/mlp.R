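# Minimal fully-connected network engine with hand-written backprop and
# an Adam optimizer. All training in this package runs through these
# functions; architectures are fixed small MLPs so explicit gradients
# are both fast and easy to verify against finite differences.

# dims: c(d_in, d_h, ..., d_out); three fully connected layers with ReLU
# on the hidden ones is the default architecture used everywhere.
new_mlp <- function(dims, zero_final = FALSE) {
  L <- length(dims) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    bound <- 1 / sqrt(dims[l]) # uniform fan-in
    W[[l]] <- matrix(runif(dims[l] * dims[l + 1], -bound, bound),
                     dims[l], dims[l + 1])
    b[[l]] <- runif(dims[l + 1], -bound, bound)
  }
  if (zero_final) {
    W[[L]][] <- 0
    b[[L]][] <- 0
  }
  list(W = W, b = b, L = L, dims = dims)
}

# cached parameter key names per (prefix, depth); avoids paste0 in the
# training hot loop
mlp_keys <- local({
  cache <- list()
  function(prefix, L) {
    id <- paste0(prefix, L)
    k <- cache[[id]]
    if (is.null(k)) {
      k <- list(W = paste0(prefix, ".W", seq_len(L)),
                b = paste0(prefix, ".b", seq_len(L)))
      cache[[id]] <<- k
    }
    k
  }
})

mlp_fwd <- function(net, X) {
  L <- net$L
  H <- vector("list", L + 1L)
  H[[1]] <- X
  for (l in seq_len(L)) {
    A <- H[[l]] %*% net$W[[l]]
    A <- sweep_add(A, net$b[[l]])
    H[[l + 1]] <- if (l < L) A * (A > 0) else A
  }
  list(out = H[[L + 1]], H = H)
}

# dout: gradient w.r.t. the (linear) output. Returns parameter grads and
# the gradient w.r.t. the input rows.
mlp_bwd <- function(net, fwd, dout) {
  L <- net$L
  dW <- vector("list", L)
  db <- vector("list", L)
  dA <- dout
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(fwd$H[[l]], dA)
    db[[l]] <- colSums(dA)
    dH <- dA %*% t(net$W[[l]])
    if (l > 1L) dA <- dH * (fwd$H[[l]] > 0) # ReLU mask (post-activation > 0)
    else dA <- dH
  }
  list(W = dW, b = db, dX = dA)
}

sweep_add <- function(A, b) {
  A + rep(b, each = nrow(A))
}

# --- covariate sub-network: one FC layer, ReLU, batch norm, dropout ----

new_covnet <- function(d_in, d_hidden = 128L, p_drop = 0.1) {
  bound <- 1 / sqrt(d_in)
  list(W = matrix(runif(d_in * d_hidden, -bound, bound), d_in, d_hidden),
       b = runif(d_hidden, -bound, bound),
       gamma = rep(1, d_hidden), beta = rep(0, d_hidden),
       run_mean = rep(0, d_hidden), run_var = rep(1, d_hidden),
       p_drop = p_drop, momentum = 0.1, eps = 1e-5)
}

covnet_fwd <- function(net, S, train = FALSE) {
  A <- sweep_add(S %*% net$W, net$b)
  R <- A * (A > 0)
  n <- nrow(R)
  if (train && n > 1L) {
    bm <- colMeans(R)
    Rc <- sweep_add(R, -bm)
    bv <- colMeans(Rc^2)
    inv <- 1 / sqrt(bv + net$eps)
    Rhat <- Rc * rep(inv, each = n)
    out <- sweep_add(Rhat * rep(net$gamma, each = n), net$beta)
    mask <- NULL
    if (net$p_drop > 0) {
      mask <- matrix(runif(length(out)) >= net$p_drop, n) / (1 - net$p_drop)
      out <- out * mask
    }
    net$run_mean <- (1 - net$momentum) * net$run_mean + net$momentum * bm
    net$run_var <- (1 - net$momentum) * net$run_var +
      net$momentum * bv * n / max(1, n - 1)
    list(out = out, S = S, R = R, Rhat = Rhat, inv = inv, mask = mask,
         net = net, train = TRUE)
  } else {
    inv <- 1 / sqrt(net$run_var + net$eps)
    Rhat <- sweep_add(R, -net$run_mean) * rep(inv, each = n)
    out <- sweep_add(Rhat * rep(net$gamma, each = n), net$beta)
    list(out = out, S = S, R = R, Rhat = Rhat, inv = inv, mask = NULL,
         net = net, train = FALSE)
  }
}

covnet_bwd <- function(net, fwd, dout) {
  n <- nrow(dout)
  if (!is.null(fwd$mask)) dout <- dout * fwd$mask
  dgamma <- colSums(dout * fwd$Rhat)
  dbeta <- colSums(dout)
  dRhat <- dout * rep(net$gamma, each = n)
  if (fwd$train && n > 1L) {
    s1 <- colSums(dRhat)
    s2 <- colSums(dRhat * fwd$Rhat)
    dR <- (dRhat - rep(s1 / n, each = n) -
             fwd$Rhat * rep(s2 / n, each = n)) * rep(fwd$inv, each = n)
  } else {
    dR <- dRhat * rep(fwd$inv, each = n)
  }
  dA <- dR * (fwd$R > 0)
  list(W = crossprod(fwd$S, dA), b = colSums(dA),
       gamma = dgamma, beta = dbeta)
}

# --- Adam ---------------------------------------------------------------

adam_new <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr
  e$beta1 <- beta1
  e$beta2 <- beta2
  e$eps <- eps
  e$t <- 0L
  e$m <- list()
  e$v <- list()
  e
}

# params/grads: flat named lists of numeric arrays. A single shared step
# counter is advanced per call; tensors absent from `grads` are left
# untouched (their moments are not decayed), so alternating objectives
# share one optimizer instance.
adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  if (opt$lr == 0) return(params)
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (key in names(grads)) {
    g <- grads[[key]]
    if (is.null(g)) next
    m <- opt$m[[key]]
    v <- opt$v[[key]]
    if (is.null(m)) {
      m <- g * 0
      v <- g * 0
    }
    m <- opt$beta1 * m + (1 - opt$beta1) * g
    v <- opt$beta2 * v + (1 - opt$beta2) * g * g
    opt$m[[key]] <- m
    opt$v[[key]] <- v
    params[[key]] <- params[[key]] -
      opt$lr * (m / bc1) / (sqrt(v / bc2) + opt$eps)
  }
  params
}

# flatten / restore helpers -----------------------------------------------

mlp_params <- function(net, prefix) {
  k <- mlp_keys(prefix, net$L)
  setNames(c(net$W, net$b), c(k$W, k$b))
}

mlp_set <- function(net, flat, prefix) {
  k <- mlp_keys(prefix, net$L)
  for (l in seq_len(net$L)) {
    net$W[[l]] <- flat[[k$W[[l]]]]
    net$b[[l]] <- flat[[k$b[[l]]]]
  }
  net
}

mlp_grads <- function(g, prefix) {
  k <- mlp_keys(prefix, length(g$W))
  setNames(c(g$W, g$b), c(k$W, k$b))
}

covnet_params <- function(net, prefix) {
  setNames(list(net$W, net$b, net$gamma, net$beta),
           paste0(prefix, c(".W", ".b", ".gamma", ".beta")))
}

covnet_set <- function(net, flat, prefix) {
  net$W <- flat[[paste0(prefix, ".W")]]
  net$b <- flat[[paste0(prefix, ".b")]]
  net$gamma <- flat[[paste0(prefix, ".gamma")]]
  net$beta <- flat[[paste0(prefix, ".beta")]]
  net
}

covnet_grads <- function(g, prefix) {
  setNames(list(g$W, g$b, g$gamma, g$beta),
           paste0(prefix, c(".W", ".b", ".gamma", ".beta")))
}
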