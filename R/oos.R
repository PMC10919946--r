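#' Out-of-sample canonical correlation by cross-validation
#'
#' The in-sample canonical correlation of a sparse fit keeps growing as
#' more (possibly irrelevant) variables are allowed in, so it is a poor
#' guide to signal. The out-of-sample version refits the model on
#' training folds and correlates the latent variables formed on held-out
#' samples with the frozen training weights, which decreases again once
#' noise variables enter.
#'
#' For each fold: the training rows are column-standardized, `k_component`
#' components are fitted (with deflation), the component-`k_component`
#' weights are frozen and sign-aligned to a full-data fit, the held-out
#' rows are standardized with the training centers/scales, and the
#' correlation of the two held-out latent variables is recorded.
#'
#' @inheritParams scca_fit
#' @param k_component which component to evaluate (deflation is applied up
#'   to it on every training fold).
#' @param folds number of folds, at least 2; every fold must hold out at
#'   least 2 samples and keep at least 3 for training.
#' @param method `"cv"` (default) or `"holdout"` (single split).
#' @param holdout_fraction test fraction for `method = "holdout"`.
#' @param full_fit optionally, an existing full-data [scca_fit()] used for
#'   sign alignment; computed internally when omitted.
#' @return an `scca_oos`: `fold_correlations`, `mean_oos` (mean over
#'   non-degenerate folds), `folds`, `fold_assignment_seed`, `k_component`.
#' @export
scca_oos <- function(pair, p_alpha, q_beta, k_component = 1L, folds = 5L,
                     seed = 1L, init = "uniform_random", tol = 1e-6,
                     max_iter = 500L, method = c("cv", "holdout"),
                     holdout_fraction = 0.3, full_fit = NULL) {
  stopifnot(inherits(pair, "scca_pair"))
  method <- match.arg(method)
  n <- nrow(pair$x1)
  k_component <- assert_count(k_component, "k_component")
  seed <- assert_count(seed, "seed", min = 0L)

  if (method == "cv") {
    folds <- assert_count(folds, "folds", min = 2L)
    if (floor(n / folds) < 2L) {
      stop("each fold must hold out at least 2 samples; reduce `folds`",
           call. = FALSE)
    }
    set.seed(seed)
    assignment <- sample(rep_len(seq_len(folds), n))
    test_sets <- split(seq_len(n), assignment)
  } else {
    if (holdout_fraction <= 0 || holdout_fraction >= 1) {
      stop("holdout_fraction must be in (0, 1)", call. = FALSE)
    }
    set.seed(seed)
    n_test <- max(2L, round(n * holdout_fraction))
    test_sets <- list(sample(seq_len(n), n_test))
    folds <- 1L
  }
  if (any(n - lengths(test_sets) < 3L)) {
    stop("each training fold must retain at least 3 samples", call. = FALSE)
  }

  if (is.null(full_fit)) {
    full_fit <- scca_fit(pair, p_alpha, q_beta, k = k_component, init = init,
                         seed = seed, tol = tol, max_iter = max_iter)
  }
  if (full_fit$k < k_component) {
    stop("full-data fit is degenerate before the requested component",
         call. = FALSE)
  }
  ref_alpha <- full_fit$alpha[, k_component]
  ref_beta <- full_fit$beta[, k_component]

  fold_cor <- vapply(seq_along(test_sets), function(i) {
    test <- test_sets[[i]]
    train <- setdiff(seq_len(n), test)
    x1_tr <- pair$x1[train, , drop = FALSE]
    x2_tr <- pair$x2[train, , drop = FALSE]
    mu1 <- colMeans(x1_tr); s1 <- apply(x1_tr, 2L, stats::sd)
    mu2 <- colMeans(x2_tr); s2 <- apply(x2_tr, 2L, stats::sd)
    s1[s1 == 0] <- 1; s2[s2 == 0] <- 1  # constant-in-fold column carries no signal
    z1 <- sweep(sweep(x1_tr, 2L, mu1, "-"), 2L, s1, "/")
    z2 <- sweep(sweep(x2_tr, 2L, mu2, "-"), 2L, s2, "/")

    fseed <- derive_seed(seed, i, stream = 3L)
    inits <- draw_inits(ncol(z1), k_component,
                        if (identical(init, "decomposition")) "uniform_constant" else init,
                        fseed)
    alpha <- beta <- NULL
    for (kk in seq_len(k_component)) {
      iv <- if (identical(init, "decomposition")) decomposition_init(z1) else inits[[kk]]
      f <- nipals_fit(z1, z2, p_alpha, q_beta, iv, tol = tol, max_iter = max_iter)
      if (f$degenerate) return(NA_real_)
      alpha <- f$alpha; beta <- f$beta
      if (kk < k_component) {
        z1 <- deflate_latent(z1, f$gamma)
        z2 <- deflate_latent(z2, f$zeta)
      }
    }
    sa <- sign(sum(alpha * ref_alpha)); if (sa == 0) sa <- 1
    sb <- sign(sum(beta * ref_beta)); if (sb == 0) sb <- 1
    u <- drop(sweep(sweep(pair$x1[test, , drop = FALSE], 2L, mu1, "-"), 2L, s1, "/") %*% (sa * alpha))
    v <- drop(sweep(sweep(pair$x2[test, , drop = FALSE], 2L, mu2, "-"), 2L, s2, "/") %*% (sb * beta))
    safe_cor(u, v)
  }, numeric(1))

  structure(list(fold_correlations = fold_cor,
                 mean_oos = mean(fold_cor, na.rm = TRUE),
                 folds = as.integer(folds),
                 fold_assignment_seed = seed,
                 k_component = k_component),
            class = "scca_oos")
}

#' @export
print.scca_oos <- function(x, ...) {
  cat(sprintf("<scca_oos> component %d: mean out-of-sample rho = %.4f over %d fold(s)\n",
              x$k_component, x$mean_oos, x$folds))
  invisible(x)
}
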