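#' Tidy a fitted model into per-sample latent coordinates
#'
#' One row per sample with its latent mean coordinates (`z1`, `z2`,
#' ...), posterior scales (`scale1`, ...) and, when available, the
#' stored label.
#'
#' @param x a `savae_fit`.
#' @param ... unused.
#' @return A tibble.
#' @method tidy savae_fit
#' @export
tidy.savae_fit <- function(x, ...) {
  J <- ncol(x$latent)
  out <- tibble::as_tibble(x$latent, .name_repair = "minimal")
  names(out) <- sprintf("z%d", seq_len(J))
  sc <- tibble::as_tibble(x$latent_scale, .name_repair = "minimal")
  names(sc) <- sprintf("scale%d", seq_len(J))
  out <- tibble::add_column(out, .sample = x$sample_ids, .before = 1)
  out <- cbind(out, sc)
  if (!is.null(x$labels)) out$.label <- x$labels
  tibble::as_tibble(out)
}

#' One-row model summary
#'
#' @param x a `savae_fit`.
#' @param ... unused.
#' @return A one-row tibble with the method, sizes, seed and final
#'   losses.
#' @method glance savae_fit
#' @export
glance.savae_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    method = x$method,
    n = nrow(x$latent),
    latent_dim = ncol(x$latent),
    epochs = max(x$history$epoch),
    recon = last$recon,
    kl = last$kl,
    umap = last$umap,
    seed = x$seed
  )
}
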