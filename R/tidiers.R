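# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a sparse CCA fit
#'
#' @param x an [scca_fit()].
#' @param all include zero weights (default: nonzero only).
#' @param ... unused.
#' @return tibble with columns `dataset` (`"x1"`/`"x2"`), `feature`,
#'   `component`, `weight`.
#' @export
tidy.scca_fit <- function(x, all = FALSE, ...) {
  long <- function(w, dataset) {
    tibble::tibble(
      dataset = dataset,
      feature = rep(rownames(w), times = ncol(w)),
      index = rep(seq_len(nrow(w)), times = ncol(w)),
      component = rep(seq_len(ncol(w)), each = nrow(w)),
      weight = as.numeric(w))
  }
  out <- dplyr::bind_rows(long(x$alpha, "x1"), long(x$beta, "x2"))
  if (!all) out <- dplyr::filter(out, .data$weight != 0)
  out
}

#' One-row summary of a sparse CCA fit
#'
#' @param x an [scca_fit()].
#' @param ... unused.
#' @return one-row tibble: dimensions, sparsity, number of components,
#'   leading canonical correlation, final plain and adjusted cumulative
#'   explained variance (block 1), convergence.
#' @export
glance.scca_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, p = x$p, q = x$q, k = x$k,
    p_alpha = x$sparsity$p_alpha, q_beta = x$sparsity$q_beta,
    rho_1 = x$rho[1],
    cpev = x$ev_1$cpev[x$k],
    cpev_adj = x$ev_1$cpev_adj[x$k],
    all_converged = all(x$converged),
    seed = x$seed)
}

#' Per-component summary of a sparse CCA fit
#'
#' @param x an [scca_fit()].
#' @return tibble with one row per component: in-sample and (if computed)
#'   out-of-sample canonical correlation, plain and adjusted CPEV for both
#'   blocks, nonzero counts, convergence.
#' @export
scca_components <- function(x) {
  stopifnot(inherits(x, "scca_fit"))
  tibble::tibble(
    component = seq_len(x$k),
    rho_insample = x$rho,
    rho_oos = if (is.null(x$rho_oos)) NA_real_ else x$rho_oos,
    cpev_1 = x$ev_1$cpev, cpev_adj_1 = x$ev_1$cpev_adj,
    cpev_2 = x$ev_2$cpev, cpev_adj_2 = x$ev_2$cpev_adj,
    nnz_alpha = vapply(x$components, function(cc) n_nonzero(cc$alpha), integer(1)),
    nnz_beta = vapply(x$components, function(cc) n_nonzero(cc$beta), integer(1)),
    n_iter = x$n_iter,
    converged = x$converged)
}

#' Tidy a permutation report
#'
#' @param x an [scca_perm_test()] result.
#' @param ... unused.
#' @return tibble without the null-draw list column.
#' @export
tidy.scca_perm <- function(x, ...) {
  tibble::as_tibble(x)[, setdiff(names(x), "null_draws")]
}

#' One-row summary of a permutation report
#'
#' @param x an [scca_perm_test()] result.
#' @param ... unused.
#' @return one-row tibble: components tested, permutations, number
#'   significant under Bonferroni at the report's alpha, and under the
#'   max-statistic rule.
#' @export
glance.scca_perm <- function(x, ...) {
  alpha <- attr(x, "alpha") %||% 0.05
  tibble::tibble(
    k = nrow(x),
    b = x$b[1],
    statistic = x$statistic[1],
    n_significant_bonferroni = sum(x$p_bonferroni <= alpha),
    n_significant_max_stat = sum(x$significant_max_stat),
    alpha = alpha)
}
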