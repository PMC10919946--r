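# Permutation-based significance testing of the canonical correlations.
#
# The key design point: every permuted refit uses exactly the same
# (p_alpha, q_beta) as the observed fit, so the null statistics are
# comparable to the observed one. A penalty-parameter method cannot
# guarantee this, because the same penalty may select different numbers of
# variables across permutations.

perm_pvalue <- function(observed, nulls) {
  (1 + sum(nulls >= observed)) / (length(nulls) + 1)
}

# Fold bookkeeping for the out-of-sample statistic: the fold assignment
# is drawn once per tested component and shared by the observed fit and
# every permutation, so all statistics are computed on identical splits
# and the block-1 training/test submatrices can be built once.
make_fold_data <- function(x1, folds, seed) {
  n <- nrow(x1)
  set.seed(seed)
  assignment <- sample(rep_len(seq_len(folds), n))
  lapply(seq_len(folds), function(fd) {
    test <- which(assignment == fd)
    train <- which(assignment != fd)
    list(train = train, test = test,
         x1_train = x1[train, , drop = FALSE],
         x1_test = x1[test, , drop = FALSE])
  })
}

# Statistic on the (possibly deflated, unstandardized) matrices: single
# component at the given sparsity, identical routine for the observed
# data (`perm` = identity) and every permuted dataset. The out-of-sample
# version fits on training rows and correlates the held-out latent
# variables; matrices are used as-is (deflated data are no longer
# column-standardizable and row permutation preserves column moments).
perm_statistic <- function(fold_data, x2, perm, p_alpha, q_beta, statistic,
                           seed, tol, max_iter) {
  # runtime guard for the equal-sparsity contract
  stopifnot(q_beta <= ncol(x2))
  set.seed(seed)
  init <- stats::runif(ncol(fold_data[[1L]]$x1_train), -1, 1)
  if (statistic == "insample") {
    x1 <- rbind(fold_data[[1L]]$x1_train, fold_data[[1L]]$x1_test)
    rows <- c(fold_data[[1L]]$train, fold_data[[1L]]$test)
    f <- nipals_fit(x1, x2[perm[rows], , drop = FALSE], p_alpha, q_beta,
                    init, tol = tol, max_iter = max_iter)
    if (f$degenerate || is.na(f$rho_insample)) return(0)
    stopifnot(n_nonzero(f$alpha) <= p_alpha, n_nonzero(f$beta) <= q_beta)
    return(f$rho_insample)
  }
  vals <- vapply(fold_data, function(fb) {
    if (length(fb$test) < 2L || length(fb$train) < 3L) return(NA_real_)
    f <- nipals_fit(fb$x1_train, x2[perm[fb$train], , drop = FALSE],
                    p_alpha, q_beta, init, tol = tol, max_iter = max_iter)
    if (f$degenerate) return(NA_real_)
    stopifnot(n_nonzero(f$alpha) <= p_alpha, n_nonzero(f$beta) <= q_beta)
    safe_cor(drop(fb$x1_test %*% f$alpha),
             drop(x2[perm[fb$test], , drop = FALSE] %*% f$beta))
  }, numeric(1))
  m <- mean(vals, na.rm = TRUE)
  if (is.nan(m)) 0 else m
}

#' Permutation test of the canonical correlations
#'
#' Tests, per component, the null hypothesis of no association between the
#' two blocks (and between their deflated counterparts for later
#' components). The rows of block 2 are shuffled, one component is
#' refitted at the *same* support sizes as the observed analysis, and the
#' chosen statistic is recorded; the observed statistic is computed by the
#' identical routine on the unshuffled data. For component k, both the
#' observed statistic and the permuted refits run on data deflated by the
#' observed first k-1 components. One-sided (greater), with the +1/+1
#' p-value convention so p is never exactly zero.
#'
#' The default statistic is the out-of-sample canonical correlation, which
#' stays near zero under noise where the in-sample one inflates.
#'
#' @inheritParams scca_fit
#' @param b number of permutations (at least 19).
#' @param statistic `"oos"` (default) or `"insample"`.
#' @param folds folds for the out-of-sample statistic.
#' @param alpha significance level used for the max-statistic flag.
#' @param keep_null keep the per-component null draws in the result.
#' @return an `scca_perm`: a tibble with one row per component
#'   (`component`, `observed`, `p_raw`, `p_bonferroni`,
#'   `significant_max_stat`, `b`, `statistic`, `seed`) and the null draws
#'   as a list column `null_draws`.
#' @export
scca_perm_test <- function(pair, p_alpha, q_beta, k = 1L, b = 100L,
                           statistic = c("oos", "insample"), folds = 5L,
                           alpha = 0.05, init = "uniform_random", seed = 1L,
                           tol = 1e-6, max_iter = 500L, keep_null = TRUE) {
  stopifnot(inherits(pair, "scca_pair"))
  statistic <- match.arg(statistic)
  b <- assert_count(b, "b", min = 19L)
  seed <- assert_count(seed, "seed", min = 0L)
  folds <- assert_count(folds, "folds", min = 2L)

  fit <- scca_fit(pair, p_alpha, q_beta, k = k, init = init, seed = seed,
                  tol = tol, max_iter = max_iter)
  k_eff <- fit$k
  n <- nrow(pair$x1)

  x1d <- pair$x1; x2d <- pair$x2
  rows <- vector("list", k_eff)
  for (kk in seq_len(k_eff)) {
    if (kk > 1L) {
      x1d <- deflate_latent(x1d, fit$components[[kk - 1L]]$gamma)
      x2d <- deflate_latent(x2d, fit$components[[kk - 1L]]$zeta)
    }
    fold_data <- make_fold_data(x1d, folds, derive_seed(seed, 0L, stream = kk))
    observed <- perm_statistic(fold_data, x2d, seq_len(n),
                               fit$sparsity$p_alpha, fit$sparsity$q_beta,
                               statistic,
                               seed = derive_seed(seed, 0L, stream = kk),
                               tol = tol, max_iter = max_iter)
    nulls <- vapply(seq_len(b), function(bb) {
      sb <- derive_seed(seed, bb, stream = kk)
      set.seed(sb)
      perm <- sample(n)
      perm_statistic(fold_data, x2d, perm,
                     fit$sparsity$p_alpha, fit$sparsity$q_beta,
                     statistic, seed = sb,
                     tol = tol, max_iter = max_iter)
    }, numeric(1))
    rows[[kk]] <- tibble::tibble(
      component = kk,
      observed = observed,
      p_raw = perm_pvalue(observed, nulls),
      p_bonferroni = NA_real_,
      significant_max_stat = NA,
      b = b,
      statistic = statistic,
      seed = seed,
      null_draws = list(nulls)
    )
  }
  rep <- structure(dplyr::bind_rows(rows), class = c("scca_perm", class(tibble::tibble())))
  rep <- adjust_multiplicity(rep, method = "bonferroni", alpha = alpha)
  rep <- adjust_multiplicity(rep, method = "max_stat", alpha = alpha)
  attr(rep, "alpha") <- alpha
  attr(rep, "keep_null") <- keep_null
  if (!keep_null) rep$null_draws <- NULL
  rep
}

#' Multiplicity adjustment for permutation reports
#'
#' `"bonferroni"` fills `p_bonferroni = min(1, K * p_raw)`. `"max_stat"`
#' flags component k significant when its observed statistic exceeds the
#' `(1 - alpha)` quantile of the null draws of the component with the
#' largest observed statistic.
#'
#' @param reports an `scca_perm` result (null draws required for
#'   `"max_stat"`).
#' @param method `"bonferroni"` or `"max_stat"`.
#' @param alpha significance level for `"max_stat"`.
#' @return the updated `scca_perm`.
#' @export
adjust_multiplicity <- function(reports, method = c("bonferroni", "max_stat"),
                                alpha = 0.05) {
  stopifnot(inherits(reports, "scca_perm"), nrow(reports) >= 1L)
  method <- match.arg(method)
  if (length(unique(reports$b)) != 1L || length(unique(reports$statistic)) != 1L) {
    stop("reports must share b and statistic kind", call. = FALSE)
  }
  if (method == "bonferroni") {
    reports$p_bonferroni <- pmin(1, nrow(reports) * reports$p_raw)
  } else {
    if (is.null(reports$null_draws)) {
      stop("max_stat adjustment needs the stored null draws", call. = FALSE)
    }
    ref <- which.max(reports$observed)
    thr <- stats::quantile(reports$null_draws[[ref]], probs = 1 - alpha,
                           names = FALSE)
    reports$significant_max_stat <- reports$observed > thr
  }
  reports
}

#' @export
print.scca_perm <- function(x, ...) {
  cat(sprintf("<scca_perm> %d component(s), B = %d, statistic = %s\n",
              nrow(x), x$b[1], x$statistic[1]))
  print(tibble::as_tibble(x)[, setdiff(names(x), "null_draws")])
  invisible(x)
}
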