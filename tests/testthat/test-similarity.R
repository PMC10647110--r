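test_that("knn_search finds exact neighbours on a line", {
  X <- matrix(c(0, 1, 2, 4), ncol = 1)
  g <- knn_search(X, k = 2)
  expect_equal(g$indices[1, ], c(2L, 3L))
  expect_equal(g$distances[1, ], c(1, 2))
  expect_equal(g$indices[4, ], c(3L, 2L))
  expect_equal(g$distances[4, ], c(2, 3))
})

test_that("knn_search with k = 1 returns the single closest other row", {
  d <- blob_data(n_per = 15, d = 3)
  g <- knn_search(d$x, k = 1)
  D <- as.matrix(dist(d$x))
  diag(D) <- Inf
  expect_equal(g$indices[, 1], unname(apply(D, 1, which.min)))
  expect_false(any(g$indices == seq_len(nrow(d$x))))
})

test_that("knn_search agrees with brute-force argsort across chunk sizes", {
  set.seed(3)
  X <- matrix(rnorm(300 * 4), 300)
  D <- as.matrix(dist(X))
  diag(D) <- Inf
  for (chunk in c(32L, 1024L)) {
    g <- knn_search(X, k = 7, chunk = chunk)
    for (i in c(1, 57, 300)) {
      expect_equal(sort(g$distances[i, ]), g$distances[i, ])
      expect_equal(g$distances[i, ], unname(sort(D[i, ])[1:7]),
                   tolerance = 1e-10)
    }
  }
})

test_that("knn_search rejects bad input", {
  X <- matrix(rnorm(20), 10)
  expect_error(knn_search(X, k = 10), "smaller")
  X[1, 1] <- NA
  expect_error(knn_search(X, k = 2), "finite")
})

test_that("calibrate_scales solves the smooth-knn equation", {
  # neighbours at distances 1, 2, 3 -> rho = 1, solve for target log2(3)
  g <- structure(list(indices = matrix(c(2L, 3L, 4L), 1),
                      distances = matrix(c(1, 2, 3), 1),
                      metric = "euclidean"), class = "neighbor_graph")
  s <- calibrate_scales(g, verbose = FALSE)
  expect_equal(s$rho, 1)
  oracle <- stats::uniroot(function(sig)
    exp(0) + exp(-1 / sig) + exp(-2 / sig) - log2(3),
    c(1e-6, 1e3), tol = 1e-12)$root
  expect_equal(s$sigma, oracle, tolerance = 1e-4)
  resid <- abs(sum(exp(-c(0, 1, 2) / s$sigma)) - log2(3))
  expect_lt(resid, 1e-4)
})

test_that("degenerate scale cases fall back to sigma = 1 and are flagged", {
  # K = 1: the single neighbour sits at rho, target log2(1) = 0 unreachable
  g1 <- structure(list(indices = matrix(2L, 1), distances = matrix(0.7, 1),
                       metric = "euclidean"), class = "neighbor_graph")
  expect_message(s1 <- calibrate_scales(g1), "degenerate")
  expect_equal(s1$sigma, 1)
  expect_equal(s1$rho, 0.7)
  expect_true(s1$degenerate)

  # all neighbours equidistant at rho: neighbour sum is K for any sigma
  g2 <- structure(list(indices = matrix(c(2L, 3L, 4L), 1),
                       distances = matrix(c(2, 2, 2), 1),
                       metric = "euclidean"), class = "neighbor_graph")
  s2 <- calibrate_scales(g2, verbose = FALSE)
  expect_true(s2$degenerate)
  expect_equal(s2$sigma, 1)

  # all-zero distances (duplicated points): rho = 0, flagged
  g3 <- structure(list(indices = matrix(c(2L, 3L), 1),
                       distances = matrix(c(0, 0), 1),
                       metric = "euclidean"), class = "neighbor_graph")
  s3 <- calibrate_scales(g3, verbose = FALSE)
  expect_equal(s3$rho, 0)
  expect_equal(s3$sigma, 1)
})

test_that("local weights are 1 at the nearest positive neighbour, 0 elsewhere", {
  d <- blob_data(n_per = 25)
  g <- knn_search(d$x, k = 5)
  s <- calibrate_scales(g, verbose = FALSE)
  w <- local_weights(g, s)
  for (i in seq_len(nrow(d$x))) {
    wi <- w[i, ]
    expect_equal(max(wi), 1) # nearest positive neighbour
    expect_equal(sum(wi > 0), 5) # only neighbour-list entries
    outside <- setdiff(seq_len(nrow(d$x)), c(i, g$indices[i, ]))
    expect_true(all(wi[outside] == 0))
  }
  # d - rho = sigma gives weight exp(-1)
  i <- 1
  j <- g$indices[i, 3]
  dij <- s$rho[i] + s$sigma[i]
  expect_equal(exp(-pmax(dij - s$rho[i], 0) / s$sigma[i]), exp(-1))
})

test_that("symmetrize applies the probabilistic t-conorm", {
  w <- Matrix::sparseMatrix(i = c(1, 2, 1, 3), j = c(2, 1, 3, 1),
                            x = c(0.5, 0.5, 1, 0.25), dims = c(3, 3))
  fg <- symmetrize(w)
  expect_equal(fg$mu[1, 2], 0.75) # 0.5 + 0.5 - 0.25
  expect_equal(fg$mu[1, 3], 1)    # 1 absorbs
  expect_equal(fg$mu[2, 3], 0)    # absent entry
  expect_identical(fg$mu, Matrix::t(fg$mu))
  expect_error(symmetrize(w * 3), "\\[0, 1\\]")
})

test_that("full pipeline matches the brute-force all-pairs oracle", {
  d <- blob_data(n_per = 100, d = 3, seed = 21)
  k <- 12
  fg <- fuzzy_graph(d$x, k = k, verbose = FALSE)
  oracle <- bruteforce_fuzzy(d$x, k = k)
  expect_lt(max(abs(as.matrix(fg$mu) - oracle)), 1e-10)
  expect_identical(fg$mu, Matrix::t(fg$mu))
  expect_true(all(fg$mu@x > 0 & fg$mu@x <= 1))
  expect_true(all(Matrix::diag(fg$mu) == 0))
  # calibration residuals
  adj <- pmax(fg$knn$distances - fg$scales$rho, 0)
  resid <- abs(rowSums(exp(-adj / fg$scales$sigma)) - log2(k))
  expect_lt(max(resid[!fg$scales$degenerate]), 1e-4)
})

test_that("fuzzy graph round-trips through the edge-list TSV", {
  d <- blob_data(n_per = 20)
  fg <- fuzzy_graph(d$x, k = 4, verbose = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fuzzy_graph(fg, path)
  header <- readLines(path, n = 1)
  expect_equal(header, "i\tj\tmu")
  fg2 <- read_fuzzy_graph(path)
  expect_equal(as.matrix(fg2$mu), as.matrix(fg$mu), tolerance = 1e-12)
})

test_that("fit_curve reproduces an independent least-squares oracle", {
  cv <- fit_curve(0.1, 1)
  d <- seq(0, 3, length.out = 300)
  y <- ifelse(d <= 0.1, 1, exp(-(d - 0.1)))
  oracle <- optim(c(1, 1), function(p)
    sum((y - 1 / (1 + p[1] * d^(2 * p[2])))^2), method = "BFGS")$par
  expect_lt(abs(cv$a - oracle[1]) / oracle[1], 1e-3)
  expect_lt(abs(cv$b - oracle[2]) / oracle[2], 1e-3)

  cv0 <- fit_curve(0, 1)
  expect_gt(cv0$a, 0)
  expect_gt(cv0$b, 0)
  dd <- seq(0, 3, length.out = 50)
  f <- 1 / (1 + cv0$a * dd^(2 * cv0$b))
  expect_equal(f[1], 1)
  expect_true(all(diff(f) < 0))
})
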