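#' Read and write count matrices
#'
#' Two on-disk layouts are supported. A directory holds Matrix Market
#' coordinate data in the genes-as-rows dialect (`matrix.mtx` with
#' companion `features.tsv` and `barcodes.tsv`, plus optional
#' `labels.tsv` and `covariates.tsv`); in memory the matrix is always
#' samples x features. A path ending in `.csv` holds a dense matrix
#' with a header row and sample ids in the first column.
#' `read_counts(write_counts(m, path))` is an exact round trip for
#' values, identifiers and order.
#'
#' @param m a [labeled_matrix].
#' @param path directory (Matrix Market) or `.csv` file path.
#' @return `write_counts` returns `path` invisibly; `read_counts`
#'   returns a [labeled_matrix].
#' @export
write_counts <- function(m, path) {
  stopifnot(inherits(m, "labeled_matrix"))
  if (grepl("\\.csv$", path)) {
    df <- as.data.frame(as.matrix(m$values))
    colnames(df) <- m$feature_ids
    df <- cbind(sample = m$sample_ids, df)
    write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  sp <- methods::as(methods::as(Matrix::t(
    Matrix::Matrix(m$values, sparse = TRUE)), "CsparseMatrix"), "generalMatrix")
  Matrix::writeMM(sp, file.path(path, "matrix.mtx"))
  writeLines(m$feature_ids, file.path(path, "features.tsv"))
  writeLines(m$sample_ids, file.path(path, "barcodes.tsv"))
  if (!is.null(m$labels))
    writeLines(as.character(m$labels), file.path(path, "labels.tsv"))
  if (!is.null(m$covariates))
    write.table(m$covariates, file.path(path, "covariates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  if (grepl("\\.csv$", path)) {
    df <- read.delim(path, sep = ",", check.names = FALSE)
    vals <- as.matrix(df[, -1, drop = FALSE])
    rownames(vals) <- NULL
    return(labeled_matrix(vals, sample_ids = as.character(df[[1]]),
                          feature_ids = colnames(df)[-1]))
  }
  mtx <- file.path(path, "matrix.mtx")
  if (!file.exists(mtx)) stop("no matrix.mtx under ", path)
  sp <- Matrix::readMM(mtx) # genes x cells on disk
  features <- readLines(file.path(path, "features.tsv"))
  barcodes <- readLines(file.path(path, "barcodes.tsv"))
  if (nrow(sp) != length(features) || ncol(sp) != length(barcodes))
    stop(sprintf(
      "dimension mismatch: matrix is %d x %d but %d features / %d barcodes",
      nrow(sp), ncol(sp), length(features), length(barcodes)))
  labels <- NULL
  lab_path <- file.path(path, "labels.tsv")
  if (file.exists(lab_path)) labels <- readLines(lab_path)
  covariates <- NULL
  cov_path <- file.path(path, "covariates.tsv")
  if (file.exists(cov_path)) covariates <- read.delim(cov_path)
  labeled_matrix(methods::as(Matrix::t(sp), "CsparseMatrix"),
                 sample_ids = barcodes, feature_ids = features,
                 labels = labels, covariates = covariates)
}

#' Write latent coordinates as TSV
#'
#' @param z latent matrix (samples x dimensions) or a `savae_fit`.
#' @param path output file.
#' @export
write_latent <- function(z, path) {
  if (inherits(z, "savae_fit")) z <- z$latent
  df <- as.data.frame(z)
  colnames(df) <- sprintf("z%d", seq_len(ncol(df)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
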