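#' Fit the low-dimensional similarity curve
#'
#' The low-dimensional similarity between embeddings at distance `d` is
#' modelled as `f(d) = 1 / (1 + a * d^(2b))`. The shape parameters
#' `(a, b)` are chosen by nonlinear least squares so that `f`
#' approximates the piecewise target
#' `t(d) = 1` for `d <= min_dist`, `exp(-(d - min_dist) / spread)`
#' otherwise, over a 300-point grid on `[0, 3 * spread]`.
#'
#' @param min_dist nonnegative; distance below which points are
#'   considered maximally similar. Default 0 (tightest packing).
#' @param spread positive scale of the target decay.
#' @return A `curve_params` list with `a`, `b`, `min_dist`, `spread`.
#' @export
fit_curve <- function(min_dist = 0, spread = 1) {
  stopifnot(min_dist >= 0, spread > 0)
  d <- seq(0, 3 * spread, length.out = 300)
  y <- ifelse(d <= min_dist, 1, exp(-(d - min_dist) / spread))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 1 / (1 + a * d^(2 * b)),
                      start = list(a = 1, b = 1),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit) || any(stats::coef(fit) <= 0)) {
    warning("curve fit failed; falling back to (a, b) = (1.577, 0.895)")
    ab <- c(a = 1.577, b = 0.895)
  } else {
    ab <- stats::coef(fit)
  }
  structure(list(a = unname(ab["a"]), b = unname(ab["b"]),
                 min_dist = min_dist, spread = spread),
            class = "curve_params")
}

#' Low-dimensional similarity between two embeddings
#'
#' `1 / (1 + a * ||z - z2||^(2b))`: equals 1 at distance zero and is
#' strictly decreasing in distance.
#'
#' @param z,z2 numeric vectors, or matrices with matching rows.
#' @param curve a `curve_params` from [fit_curve()].
#' @return Similarity value(s) in `(0, 1]`.
#' @export
low_dim_similarity <- function(z, z2, curve) {
  if (is.matrix(z)) d2 <- rowSums((z - z2)^2) else d2 <- sum((z - z2)^2)
  1 / (1 + curve$a * d2^curve$b)
}
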