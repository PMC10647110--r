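#' Input transforms for encoder networks
#'
#' `log1p` maps counts to `log(1 + x)` (the encoder-input representation
#' used for count likelihoods); `binarize` rescales by the data maximum
#' and thresholds at 0.5; `identity` passes data through.
#'
#' @param m matrix or [labeled_matrix].
#' @param mode `"identity"`, `"log1p"` or `"binarize"`.
#' @return A dense numeric matrix.
#' @export
transform_input <- function(m, mode = c("identity", "log1p", "binarize")) {
  mode <- match.arg(mode)
  x <- lm_dense(m)
  if (mode != "identity" && any(x < 0))
    stop("negative input to ", mode, " transform")
  switch(mode,
    identity = x,
    log1p = log1p(x),
    binarize = {
      mx <- max(x)
      if (mx == 0) x else (x / mx >= 0.5) * 1
    }
  )
}

#' Select highly variable genes
#'
#' Ranks features by their dispersion (variance over mean of
#' total-count-normalized expression), standardized within 20
#' equal-frequency mean bins so that the mean--dispersion trend of
#' count noise cancels out, and keeps the top `n_top` features in
#' their original column order. Each cell is scaled to the median
#' total count before the statistics are computed.
#'
#' @param m a [labeled_matrix] (or matrix) of nonnegative counts.
#' @param n_top number of features to keep.
#' @param n_bins number of equal-frequency mean bins.
#' @return A [labeled_matrix] restricted to the selected features, with
#'   attribute `"hvg_rank"` giving the selected columns' rank order.
#' @export
select_hvg <- function(m, n_top = 1200L, n_bins = 20L) {
  lm <- if (inherits(m, "labeled_matrix")) m else labeled_matrix(m)
  x <- lm_dense(lm)
  p <- ncol(x)
  if (n_top > p) stop("n_top exceeds the number of features")
  totals <- rowSums(x)
  totals[totals == 0] <- 1
  xn <- x / totals * stats::median(rowSums(x))
  mu <- colMeans(xn)
  v <- colSums((xn - rep(mu, each = nrow(xn)))^2) / (nrow(xn) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)

  n_bins <- max(1L, min(n_bins, p))
  bins <- cut(rank(mu, ties.method = "first"),
              breaks = n_bins, labels = FALSE, include.lowest = TRUE)
  zdisp <- disp
  for (bb in unique(bins)) {
    sel <- bins == bb
    s <- sd(disp[sel])
    if (!is.finite(s) || s == 0) s <- 1
    zdisp[sel] <- (disp[sel] - mean(disp[sel])) / s
  }
  # features constant on the raw scale are uninformative and rank last
  raw_var <- colSums((x - rep(colMeans(x), each = nrow(x)))^2)
  zdisp[disp == 0 | raw_var == 0] <- -Inf
  ord <- order(zdisp, decreasing = TRUE)
  keep <- sort(ord[seq_len(n_top)])
  out <- labeled_matrix(lm$values[, keep, drop = FALSE],
                        sample_ids = lm$sample_ids,
                        feature_ids = lm$feature_ids[keep],
                        labels = lm$labels, covariates = lm$covariates)
  attr(out, "hvg_rank") <- match(keep, ord)
  out
}
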