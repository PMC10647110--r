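#' Sample-by-feature matrix with ids, labels and covariates
#'
#' The basic data container used throughout the package: a numeric matrix
#' with rows as samples and columns as features, together with sample and
#' feature identifiers, optional per-sample class labels (used for
#' evaluation only, never during training) and an optional covariate
#' table. Count matrices may be sparse (`Matrix::dgCMatrix`).
#'
#' @param values numeric matrix or `dgCMatrix`, samples in rows.
#' @param sample_ids,feature_ids character vectors matching the matrix
#'   dimensions; generated when omitted.
#' @param labels optional per-sample labels (factor, character or integer).
#' @param covariates optional per-sample covariate data frame.
#'
#' @return An object of class `labeled_matrix`.
#' @export
labeled_matrix <- function(values, sample_ids = NULL, feature_ids = NULL,
                           labels = NULL, covariates = NULL) {
  stopifnot(length(dim(values)) == 2)
  n <- nrow(values)
  p <- ncol(values)
  sample_ids <- sample_ids %||% rownames(values) %||% sprintf("sample_%d", seq_len(n))
  feature_ids <- feature_ids %||% colnames(values) %||% sprintf("feature_%d", seq_len(p))
  if (length(sample_ids) != n) stop("sample_ids length does not match rows")
  if (length(feature_ids) != p) stop("feature_ids length does not match columns")
  if (!is.null(labels) && length(labels) != n)
    stop("labels length does not match rows")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("covariates rows do not match samples")
  }
  structure(
    list(values = values, sample_ids = as.character(sample_ids),
         feature_ids = as.character(feature_ids), labels = labels,
         covariates = covariates),
    class = "labeled_matrix"
  )
}

#' @export
dim.labeled_matrix <- function(x) dim(x$values)

#' @export
print.labeled_matrix <- function(x, ...) {
  cat(sprintf("<labeled_matrix> %d samples x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              if (methods::is(x$values, "sparseMatrix")) "sparse" else "dense"))
  if (!is.null(x$labels))
    cat("  labels: ", paste(head(unique(as.character(x$labels)), 8), collapse = ", "),
        "\n", sep = "")
  if (!is.null(x$covariates))
    cat("  covariates: ", paste(names(x$covariates), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname labeled_matrix
#' @param x a `labeled_matrix`.
#' @param ... unused.
#' @method as_tibble labeled_matrix
#' @export
as_tibble.labeled_matrix <- function(x, ...) {
  out <- tibble::as_tibble(as.matrix(x$values), .name_repair = "minimal")
  names(out) <- x$feature_ids
  out <- tibble::add_column(out, .sample = x$sample_ids, .before = 1)
  if (!is.null(x$labels)) out$.label <- x$labels
  out
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

# internal: dense numeric matrix view
lm_dense <- function(x) {
  if (inherits(x, "labeled_matrix")) x <- x$values
  as.matrix(x)
}
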