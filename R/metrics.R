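#' Canonical correlation of a weight pair
#'
#' Computes \eqn{\rho = \alpha^T X_1^T X_2 \beta /
#' \sqrt{\alpha^T X_1^T X_1 \alpha}\sqrt{\beta^T X_2^T X_2 \beta}}. On
#' column-centered data this equals the Pearson correlation of the two
#' latent variables \eqn{X_1\alpha} and \eqn{X_2\beta}.
#'
#' @param alpha,beta weight vectors for the two blocks.
#' @param pair an [scca_pair][scca_standardize].
#' @return a single correlation in \[-1, 1\].
#' @export
canonical_cor <- function(alpha, beta, pair) {
  stopifnot(inherits(pair, "scca_pair"))
  u <- drop(pair$x1 %*% alpha)
  v <- drop(pair$x2 %*% beta)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("latent variable has zero norm; weights give no projection",
         call. = FALSE)
  }
  sum(u * v) / (nu * nv)
}

#' Cumulative proportion of explained variance (CPEV)
#'
#' Entry k is \eqn{tr(G_k^T G_k) / tr(X^T X)} where `G_k` stacks the first
#' k latent variables. With latent variables computed from unit-norm
#' weight vectors on the original matrix (the package default), this is
#' the share of total variance the components carry; it is non-decreasing
#' in k because the denominator is fixed at the original matrix.
#'
#' @param latents n-by-K matrix of latent variables (one column per
#'   component).
#' @param x the original data matrix the latents were computed against.
#' @return length-K numeric vector of cumulative fractions.
#' @export
cpev <- function(latents, x) {
  latents <- as.matrix(latents)
  if (nrow(latents) != nrow(x)) {
    stop("latents and x must have the same number of rows", call. = FALSE)
  }
  cumsum(colSums(latents^2)) / sum(x^2)
}

#' Adjust CPEV for correlated components
#'
#' Sparse weights break the orthogonality of latent variables across
#' components, so plain CPEV can count the same variance twice. The
#' adjusted measure discounts component k by the factor
#' \eqn{\prod_{i<k} (1 - |cor(\gamma_i, \gamma_k)|)}: a component
#' perfectly correlated with an earlier one contributes nothing, an
#' uncorrelated one is untouched.
#'
#' @param cpev length-K vector of cumulative explained-variance fractions.
#' @param latents the n-by-K latent matrix the adjustment correlations are
#'   computed from.
#' @return an `scca_ev` object: list with `cpev`, `cpev_adj`, and the K-by-K
#'   absolute correlation matrix `cross_component_cor`.
#' @export
cpev_adjusted <- function(cpev, latents) {
  latents <- as.matrix(latents)
  k <- ncol(latents)
  if (length(cpev) != k) stop("length(cpev) must equal ncol(latents)", call. = FALSE)
  if (k < 1L) stop("need at least one component", call. = FALSE)
  sds <- apply(latents, 2L, stats::sd)
  cc <- diag(1, k)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in seq((i + 1L), k)) {
        r <- if (sds[i] == 0 || sds[j] == 0) 0 else abs(stats::cor(latents[, i], latents[, j]))
        cc[i, j] <- cc[j, i] <- r
      }
    }
  }
  adj <- vapply(seq_len(k), function(kk) {
    if (kk == 1L) cpev[1L] else cpev[kk] * prod(1 - cc[seq_len(kk - 1L), kk])
  }, numeric(1))
  structure(list(cpev = as.numeric(cpev), cpev_adj = adj,
                 cross_component_cor = cc),
            class = "scca_ev")
}

#' @export
print.scca_ev <- function(x, ...) {
  cat("<scca_ev>\n")
  print(tibble::tibble(component = seq_along(x$cpev),
                       cpev = x$cpev, cpev_adj = x$cpev_adj))
  invisible(x)
}
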