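# Alternating NIPALS loop with rank-based soft-thresholding.
#
# nipals_fit() is the computational workhorse: it takes bare matrices (not
# necessarily standardized -- deflated and permuted matrices are fitted
# as-is) and returns a plain list. scca_component() is the user-facing
# wrapper around a standardized pair.

nipals_fit <- function(x1, x2, p_alpha, q_beta, init,
                       tol = 1e-6, max_iter = 500L) {
  p <- ncol(x1); q <- ncol(x2)
  p_alpha <- assert_count(p_alpha, "p_alpha")
  q_beta <- assert_count(q_beta, "q_beta")
  if (p_alpha > p) stop("p_alpha exceeds ncol(x1)", call. = FALSE)
  if (q_beta > q) stop("q_beta exceeds ncol(x2)", call. = FALSE)
  if (length(init) != p || all(init == 0)) {
    stop("init must be a length-p vector with a nonzero entry", call. = FALSE)
  }
  if (!is.numeric(tol) || tol <= 0) stop("tol must be > 0", call. = FALSE)
  max_iter <- assert_count(max_iter, "max_iter")

  raw <- nipals_core(x1, x2, p_alpha, q_beta, init, tol, as.integer(max_iter))

  out <- list(alpha = raw$alpha, beta = raw$beta,
              gamma = raw$gamma, zeta = raw$zeta,
              rho_insample = NA_real_, n_iter = raw$n_iter,
              converged = raw$converged, degenerate = raw$degenerate,
              tie_alpha = raw$tie_alpha, tie_beta = raw$tie_beta,
              rho_trace = raw$rho_trace)
  if (out$degenerate) {
    out$alpha <- numeric(p); out$beta <- numeric(q)
    out$gamma <- numeric(nrow(x1)); out$zeta <- numeric(nrow(x2))
    return(out)
  }

  # reproducible sign: flip the whole component so the largest-magnitude
  # alpha entry is positive (rho is unchanged)
  s <- sign(out$alpha[which.max(abs(out$alpha))])
  if (s == 0) s <- 1
  out$alpha <- unit_norm(s * out$alpha)
  out$beta <- unit_norm(s * out$beta)
  out$gamma <- s * out$gamma
  out$zeta <- s * out$zeta
  out$rho_insample <- safe_cor(out$gamma, out$zeta)
  out
}

# Draw the k initial alpha vectors for a fit, before any other RNG use, so
# that per-level path fits and single fits share inits exactly.
draw_inits <- function(p, k, init, seed) {
  init <- match.arg(init, c("uniform_random", "uniform_constant", "decomposition"))
  if (init == "uniform_random") {
    set.seed(seed)
    lapply(seq_len(k), function(i) stats::runif(p, -1, 1))
  } else if (init == "uniform_constant") {
    lapply(seq_len(k), function(i) rep(1 / sqrt(p), p))
  } else {
    # data-dependent; resolved at fit time against the current deflated x1
    vector("list", k)
  }
}

decomposition_init <- function(x1) {
  drop(svd(x1, nu = 0L, nv = 1L)$v)
}

#' Fit a single sparse canonical component
#'
#' One pass of the alternating NIPALS loop with rank-based
#' soft-thresholding at fixed support sizes `(p_alpha, q_beta)`. The loop
#' alternates: latent variable for block 1, least-squares weights for
#' block 2 (thresholded), latent for block 2, weights for block 1
#' (thresholded), stopping when the in-sample canonical correlation
#' changes by at most `tol`.
#'
#' @param pair an [scca_pair][scca_standardize].
#' @param p_alpha,q_beta target nonzero counts for the block-1 and block-2
#'   weight vectors.
#' @param init either a numeric length-p starting vector or one of
#'   `"uniform_random"`, `"uniform_constant"`, `"decomposition"`.
#' @param seed integer seed used when `init` is `"uniform_random"`.
#' @param tol convergence tolerance on successive canonical correlations.
#' @param max_iter iteration cap; non-convergence is flagged, not an error.
#' @return an `scca_component`: unit-norm weight vectors `alpha`, `beta`,
#'   unit-norm latent variables `gamma`, `zeta`, `rho_insample`, `n_iter`,
#'   `converged`, `degenerate` and tie flags.
#' @export
scca_component <- function(pair, p_alpha, q_beta, init = "uniform_random",
                           seed = 1L, tol = 1e-6, max_iter = 500L) {
  stopifnot(inherits(pair, "scca_pair"))
  p <- ncol(pair$x1)
  if (is.numeric(init)) {
    init_vec <- init
  } else if (identical(init, "decomposition")) {
    init_vec <- decomposition_init(pair$x1)
  } else {
    init_vec <- draw_inits(p, 1L, init, seed)[[1L]]
  }
  fit <- nipals_fit(pair$x1, pair$x2, p_alpha, q_beta, init_vec,
                    tol = tol, max_iter = max_iter)
  fit$p_alpha <- as.integer(p_alpha)
  fit$q_beta <- as.integer(q_beta)
  fit$rho_oos <- NULL
  class(fit) <- "scca_component"
  fit
}

#' @export
print.scca_component <- function(x, ...) {
  cat(sprintf(
    "<scca_component> rho = %.4f, nnz = (%d, %d), %s in %d iterations\n",
    x$rho_insample, n_nonzero(x$alpha), n_nonzero(x$beta),
    if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}
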