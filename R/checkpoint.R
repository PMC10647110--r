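#' Save and restore model checkpoints
#'
#' A checkpoint directory holds the parameter archive
#' (`params.rds`) and a plain-JSON sidecar (`checkpoint.json`)
#' recording the network sizes, likelihood family, input transform,
#' training configuration and seed, so a run can be audited without
#' loading the archive.
#'
#' @param fit a `savae_fit` (or a bare `savae_model`).
#' @param dir checkpoint directory (created if missing).
#' @return `save_checkpoint` returns `dir` invisibly;
#'   `load_checkpoint` returns the restored `savae_model` with the
#'   sidecar in attribute `"meta"`.
#' @export
save_checkpoint <- function(fit, dir) {
  model <- if (inherits(fit, "savae_fit")) fit$model else fit
  stopifnot(inherits(model, "savae_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "params.rds"))
  meta <- list(
    network = list(input_dim = model$input_dim,
                   latent_dim = model$latent_dim,
                   hidden_dim = model$hidden_dim,
                   depth = model$enc$L, activation = "relu"),
    likelihood = list(family = model$spec$family,
                      learn_r = model$spec$learn_r),
    transform = model$transform,
    conditional = model$cov_dim > 0,
    conditional_encoder = model$conditional_encoder,
    config = if (inherits(fit, "savae_fit")) fit$config else NULL,
    seed = if (inherits(fit, "savae_fit")) fit$seed else NULL
  )
  jsonlite::write_json(meta, file.path(dir, "checkpoint.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  model <- readRDS(file.path(dir, "params.rds"))
  if (!inherits(model, "savae_model")) stop("not a model checkpoint")
  meta <- jsonlite::read_json(file.path(dir, "checkpoint.json"))
  attr(model, "meta") <- meta
  model
}
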