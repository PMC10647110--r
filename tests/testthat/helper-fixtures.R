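# Shared fixtures and small numerical utilities for the test suite.

# tiny deterministic data cloud: two Gaussian blobs in d dimensions
blob_data <- function(n_per = 30, d = 2, sep = 4, seed = 11) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * d), n_per),
             matrix(rnorm(n_per * d, mean = sep), n_per))
  list(x = x, labels = rep(0:1, each = n_per))
}

# brute-force fuzzy-graph oracle: enumerates all pairs, solves sigma
# with uniroot, and symmetrizes densely. Independent of the package's
# vectorised path.
bruteforce_fuzzy <- function(X, k, target = log2(k)) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nbr <- setdiff(order(replace(D[i, ], i, Inf)), i)[seq_len(k)]
    d <- D[i, nbr]
    rho <- if (any(d > 0)) min(d[d > 0]) else 0
    adj <- pmax(d - rho, 0)
    if (all(adj == 0)) {
      sigma <- 1
    } else {
      f <- function(s) sum(exp(-adj / s)) - target
      sigma <- stats::uniroot(f, c(1e-12, 1e9), tol = 1e-14)$root
    }
    W[i, nbr] <- exp(-adj / sigma)
  }
  W + t(W) - W * t(W)
}

# finite-difference gradient of a scalar function of a flat param list
numeric_grad <- function(fn, params, h = 1e-5) {
  grads <- params
  for (key in names(params)) {
    g <- params[[key]]
    for (i in seq_along(g)) {
      up <- params
      dn <- params
      up[[key]][i] <- up[[key]][i] + h
      dn[[key]][i] <- dn[[key]][i] - h
      g[i] <- (fn(up) - fn(dn)) / (2 * h)
    }
    grads[[key]] <- g
  }
  grads
}

max_rel_err <- function(a, b, floor = 1e-4) {
  stopifnot(identical(names(a), names(b)))
  m <- 0
  for (key in names(a))
    m <- max(m, max(abs(a[[key]] - b[[key]]) /
                      pmax(abs(a[[key]]) + abs(b[[key]]), floor)))
  m
}
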