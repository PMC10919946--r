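#' Fit a sparse CCA model with K components
#'
#' Sequentially estimates `k` canonical components by the soft-thresholded
#' NIPALS loop, deflating each block by its own latent variable between
#' components so later components describe remaining structure. After
#' fitting, cumulative explained variance (plain and adjusted for
#' cross-component correlation) is computed for both blocks, and, when
#' `folds` is given, an out-of-sample canonical correlation per component.
#'
#' @param pair an [scca_pair][scca_standardize].
#' @param p_alpha,q_beta target nonzero counts for the two weight vectors
#'   (applied to every component).
#' @param k number of components, `k <= min(p, q)`.
#' @param init initialization: `"uniform_random"` (i.i.d. uniform on
#'   (-1, 1), seeded), `"uniform_constant"` (all `1/sqrt(p)`), or
#'   `"decomposition"` (leading right singular vector of the current,
#'   possibly deflated, block-1 matrix).
#' @param seed integer; drives initialization and fold assignment.
#' @param tol,max_iter NIPALS stopping rule: iterate until the in-sample
#'   canonical correlation changes by at most `tol`, capped at `max_iter`.
#' @param folds `NULL` (skip) or number of cross-validation folds for the
#'   out-of-sample canonical correlation of each component.
#' @param cpev_convention `"weights_unit"` (default): explained variance
#'   from un-normalized latents `X %*% alpha` with unit-norm weights;
#'   `"latents_unit"`: the literal unit-norm-latent formula, which reduces
#'   to `k / tr(X'X)` and is kept only for comparability.
#' @return an object of class `scca_fit`; see [tidy.scca_fit()],
#'   [glance.scca_fit()], [autoplot.scca_fit()].
#' @examples
#' sim <- scca_simulate(scca_design(n = 60, p = 40, q = 30, k_true = 1,
#'                                  support_sizes_1 = 10, support_sizes_2 = 8,
#'                                  latent_sd = 3, seed = 1))
#' pair <- scca_standardize(sim$x1, sim$x2)
#' fit <- scca_fit(pair, p_alpha = 10, q_beta = 8, k = 1, seed = 1)
#' fit$rho
#' @export
scca_fit <- function(pair, p_alpha, q_beta, k = 1L,
                     init = "uniform_random", seed = 1L,
                     tol = 1e-6, max_iter = 500L, folds = NULL,
                     cpev_convention = c("weights_unit", "latents_unit")) {
  stopifnot(inherits(pair, "scca_pair"))
  cpev_convention <- match.arg(cpev_convention)
  p <- ncol(pair$x1); q <- ncol(pair$x2)
  k <- assert_count(k, "k")
  if (k > min(p, q)) stop("k must not exceed min(p, q)", call. = FALSE)
  seed <- assert_count(seed, "seed", min = 0L)
  init <- match.arg(init, c("uniform_random", "uniform_constant",
                            "decomposition"))
  inits <- draw_inits(p, k, init, seed)

  x1d <- pair$x1; x2d <- pair$x2
  comps <- vector("list", k)
  n_done <- 0L
  for (kk in seq_len(k)) {
    iv <- if (identical(init, "decomposition")) decomposition_init(x1d) else inits[[kk]]
    f <- nipals_fit(x1d, x2d, p_alpha, q_beta, iv,
                    tol = tol, max_iter = max_iter)
    if (f$degenerate) {
      warning(sprintf("component %d is degenerate (thresholding removed all weights); truncating at %d component(s)",
                      kk, n_done), call. = FALSE)
      break
    }
    if (f$tie_alpha || f$tie_beta) {
      warning(sprintf("component %d: tie at the threshold boundary; support may be sparser than requested", kk),
              call. = FALSE)
    }
    comps[[kk]] <- f
    n_done <- kk
    if (kk < k) {
      x1d <- deflate_latent(x1d, f$gamma)
      x2d <- deflate_latent(x2d, f$zeta)
    }
  }
  comps <- comps[seq_len(n_done)]
  if (n_done == 0L) stop("no non-degenerate component could be estimated", call. = FALSE)

  fit <- assemble_fit(pair, comps, p_alpha = as.integer(p_alpha),
                      q_beta = as.integer(q_beta), k_requested = k,
                      init = init, seed = seed, tol = tol,
                      max_iter = as.integer(max_iter),
                      cpev_convention = cpev_convention)

  if (!is.null(folds)) {
    fit$folds <- as.integer(folds)
    fit$rho_oos <- vapply(seq_len(n_done), function(kk) {
      scca_oos(pair, p_alpha, q_beta, k_component = kk, folds = folds,
               seed = derive_seed(seed, kk, stream = 2L), init = init,
               tol = tol, max_iter = max_iter, full_fit = fit)$mean_oos
    }, numeric(1))
    for (kk in seq_len(n_done)) fit$components[[kk]]$rho_oos <- fit$rho_oos[kk]
  }
  fit
}

# Shared post-processing: weight matrices, original-space latents,
# explained variance, and the scca_fit container. Used by both scca_fit()
# and scca_path() so a path level is identical to a standalone fit.
assemble_fit <- function(pair, comps, p_alpha, q_beta, k_requested,
                         init, seed, tol, max_iter, cpev_convention) {
  k <- length(comps)
  A <- vapply(comps, `[[`, numeric(ncol(pair$x1)), "alpha")
  B <- vapply(comps, `[[`, numeric(ncol(pair$x2)), "beta")
  dim(A) <- c(ncol(pair$x1), k); dim(B) <- c(ncol(pair$x2), k)
  dimnames(A) <- list(pair$feature_names_1, paste0("comp_", seq_len(k)))
  dimnames(B) <- list(pair$feature_names_2, paste0("comp_", seq_len(k)))
  G <- pair$x1 %*% A
  H <- pair$x2 %*% B
  if (identical(cpev_convention, "latents_unit")) {
    G <- apply(G, 2L, unit_norm); H <- apply(H, 2L, unit_norm)
    dim(G) <- c(nrow(pair$x1), k); dim(H) <- c(nrow(pair$x2), k)
  }
  structure(list(
    components = comps,
    k = k,
    k_requested = as.integer(k_requested),
    sparsity = list(p_alpha = p_alpha, q_beta = q_beta),
    init = init, seed = as.integer(seed), tol = tol,
    max_iter = max_iter, folds = NULL,
    alpha = A, beta = B,
    latents_1 = G, latents_2 = H,
    rho = vapply(comps, `[[`, numeric(1), "rho_insample"),
    rho_oos = NULL,
    ev_1 = cpev_adjusted(cpev(G, pair$x1), G),
    ev_2 = cpev_adjusted(cpev(H, pair$x2), H),
    cpev_convention = cpev_convention,
    n = nrow(pair$x1), p = ncol(pair$x1), q = ncol(pair$x2),
    converged = vapply(comps, `[[`, logical(1), "converged"),
    n_iter = vapply(comps, `[[`, integer(1), "n_iter")
  ), class = "scca_fit")
}

#' @export
print.scca_fit <- function(x, ...) {
  cat(sprintf("<scca_fit> %d component(s), sparsity (p_alpha = %d, q_beta = %d), n = %d, p = %d, q = %d\n",
              x$k, x$sparsity$p_alpha, x$sparsity$q_beta, x$n, x$p, x$q))
  tab <- tibble::tibble(
    component = seq_len(x$k),
    rho = x$rho,
    rho_oos = if (is.null(x$rho_oos)) NA_real_ else x$rho_oos,
    cpev = x$ev_1$cpev,
    cpev_adj = x$ev_1$cpev_adj,
    nnz_alpha = vapply(x$components, function(cc) n_nonzero(cc$alpha), integer(1)),
    nnz_beta = vapply(x$components, function(cc) n_nonzero(cc$beta), integer(1)),
    converged = x$converged
  )
  print(tab)
  invisible(x)
}
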