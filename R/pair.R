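#' Column-standardize two data blocks sharing samples
#'
#' Centers every column to mean zero and scales to unit standard deviation
#' (divisor `n - 1`), for both matrices, and bundles them with their sample
#' identifiers and feature names. All model-fitting functions in the
#' package take the resulting pair object.
#'
#' @param x1,x2 numeric matrices (or all-numeric data frames) with the same
#'   number of rows, samples in rows and features in columns. No missing
#'   values; no constant columns.
#' @param sample_ids optional character vector of row identifiers; defaults
#'   to the rownames of `x1`, or `S1, S2, ...`.
#' @return an object of class `scca_pair`: a list with elements `x1`, `x2`
#'   (standardized matrices), `sample_ids`, `feature_names_1`,
#'   `feature_names_2`.
#' @examples
#' p <- scca_standardize(matrix(rnorm(30), 10), matrix(rnorm(20), 10))
#' colMeans(p$x1)  # ~0
#' @export
scca_standardize <- function(x1, x2, sample_ids = NULL) {
  x1 <- as_numeric_matrix(x1, "x1")
  x2 <- as_numeric_matrix(x2, "x2")
  if (nrow(x1) != nrow(x2)) {
    stop(sprintf("x1 and x2 must share rows: %d vs %d", nrow(x1), nrow(x2)),
         call. = FALSE)
  }
  n <- nrow(x1)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  ids <- sample_ids %||% rownames(x1) %||% sprintf("S%d", seq_len(n))
  if (length(ids) != n) stop("sample_ids length does not match rows", call. = FALSE)

  out <- structure(
    list(
      x1 = standardize_columns(x1, "x1"),
      x2 = standardize_columns(x2, "x2"),
      sample_ids = as.character(ids),
      feature_names_1 = colnames(x1) %||% sprintf("x1_%d", seq_len(ncol(x1))),
      feature_names_2 = colnames(x2) %||% sprintf("x2_%d", seq_len(ncol(x2)))
    ),
    class = "scca_pair"
  )
  rownames(out$x1) <- rownames(out$x2) <- out$sample_ids
  colnames(out$x1) <- out$feature_names_1
  colnames(out$x2) <- out$feature_names_2
  out
}

as_numeric_matrix <- function(x, name) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
  if (anyNA(x)) stop(sprintf("`%s` contains missing values", name), call. = FALSE)
  x
}

standardize_columns <- function(x, name) {
  mu <- colMeans(x)
  s <- apply(x, 2L, stats::sd)
  if (any(s == 0)) {
    bad <- (colnames(x) %||% as.character(seq_len(ncol(x))))[which(s == 0)]
    stop(sprintf("constant column(s) in `%s`: %s", name,
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  sweep(sweep(x, 2L, mu, "-"), 2L, s, "/")
}

#' @export
print.scca_pair <- function(x, ...) {
  cat(sprintf("<scca_pair> %d samples; x1: %d features, x2: %d features\n",
              nrow(x$x1), ncol(x$x1), ncol(x$x2)))
  invisible(x)
}

#' Project a latent variable out of a data matrix
#'
#' Deflation step between components: returns
#' \eqn{(I_n - \gamma\gamma^T/\gamma^T\gamma)\,X}, so every column of the
#' result is orthogonal to `latent`. Applied to each block with its own
#' latent variable before estimating the next component.
#'
#' @param x numeric matrix, n rows.
#' @param latent numeric length-n vector with nonzero norm.
#' @return matrix of the same shape with `latent` projected out.
#' @export
deflate_latent <- function(x, latent) {
  if (length(latent) != nrow(x)) {
    stop("latent length must equal nrow(x)", call. = FALSE)
  }
  ss <- sum(latent^2)
  if (ss == 0) stop("latent vector has zero norm", call. = FALSE)
  x - latent %*% (crossprod(latent, x) / ss)
}
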