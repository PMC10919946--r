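#' Run a replicated simulation experiment
#'
#' Loops generate -> standardize -> fit -> (optionally) test, score and
#' check support nestedness over independent replicates of a design, with
#' per-replicate seeds derived from one master seed. The output tables are
#' tidy, one row per replicate/component, ready for summarising or
#' plotting.
#'
#' @param design an [scca_design()]; its `seed` field is overridden per
#'   replicate.
#' @param p_alpha,q_beta support sizes used for fitting.
#' @param k number of components to fit.
#' @param replicates number of independent datasets.
#' @param b permutations per replicate (`NULL` skips testing).
#' @param statistic,folds,alpha passed to [scca_perm_test()].
#' @param grid_p_alpha optional vector of block-1 support sizes; when
#'   given, a sparsity path is fitted per replicate and support
#'   nestedness recorded.
#' @param score score recovery against the ground truth (requires
#'   `k_true >= 1`).
#' @param seed master seed.
#' @param tol,max_iter NIPALS stopping rule.
#' @return list of class `scca_experiment` with tibbles `recovery`,
#'   `tests`, `explained`, `nestedness` (empty tibbles where a stage was
#'   skipped) and `failed` (replicates whose fit errored).
#' @export
scca_experiment <- function(design, p_alpha, q_beta, k = 1L, replicates = 10L,
                            b = NULL, statistic = "oos", folds = 5L,
                            alpha = 0.05, grid_p_alpha = NULL, score = TRUE,
                            seed = 1L, tol = 1e-6, max_iter = 500L) {
  stopifnot(inherits(design, "scca_design"))
  replicates <- assert_count(replicates, "replicates")
  seed <- assert_count(seed, "seed", min = 0L)

  recovery <- list(); tests <- list(); explained <- list(); nested <- list()
  failed <- integer(0)

  for (r in seq_len(replicates)) {
    rseed <- derive_seed(seed, r, stream = 11L)
    d <- design
    d$seed <- rseed
    res <- tryCatch({
      sim <- scca_simulate(d)
      pair <- scca_standardize(sim$x1, sim$x2)
      fit <- suppressWarnings(
        scca_fit(pair, p_alpha, q_beta, k = k, seed = rseed,
                 tol = tol, max_iter = max_iter))
      out <- list()
      out$explained <- tibble::tibble(
        replicate = r, component = seq_len(fit$k),
        rho = fit$rho, cpev = fit$ev_1$cpev, cpev_adj = fit$ev_1$cpev_adj)
      if (score && design$k_true >= 1L) {
        out$recovery <- dplyr::mutate(scca_score(fit, sim$truth),
                                      replicate = r, .before = 1L)
      }
      if (!is.null(b)) {
        pt <- scca_perm_test(pair, p_alpha, q_beta, k = k, b = b,
                             statistic = statistic, folds = folds,
                             alpha = alpha, seed = rseed,
                             tol = tol, max_iter = max_iter,
                             keep_null = FALSE)
        out$tests <- tibble::tibble(
          replicate = r, component = pt$component, observed = pt$observed,
          p_raw = pt$p_raw, p_bonferroni = pt$p_bonferroni,
          significant_max_stat = pt$significant_max_stat,
          reject_raw = pt$p_raw <= alpha,
          reject_bonferroni = pt$p_bonferroni <= alpha)
      }
      if (!is.null(grid_p_alpha)) {
        path <- suppressWarnings(
          scca_path(pair, p_alpha = grid_p_alpha, q_beta = q_beta, k = k,
                    seed = rseed, tol = tol, max_iter = max_iter))
        out$nested <- dplyr::mutate(support_nested(path), replicate = r,
                                    .before = 1L)
      }
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("replicate %d failed: %s", r, conditionMessage(res)),
              call. = FALSE)
      failed <- c(failed, r)
      next
    }
    explained[[length(explained) + 1L]] <- res$explained
    if (!is.null(res$recovery)) recovery[[length(recovery) + 1L]] <- res$recovery
    if (!is.null(res$tests)) tests[[length(tests) + 1L]] <- res$tests
    if (!is.null(res$nested)) nested[[length(nested) + 1L]] <- res$nested
  }

  structure(list(recovery = dplyr::bind_rows(recovery),
                 tests = dplyr::bind_rows(tests),
                 explained = dplyr::bind_rows(explained),
                 nestedness = dplyr::bind_rows(nested),
                 failed = failed,
                 config = list(design = design, p_alpha = p_alpha,
                               q_beta = q_beta, k = k,
                               replicates = replicates, b = b,
                               statistic = statistic, folds = folds,
                               alpha = alpha, grid_p_alpha = grid_p_alpha,
                               seed = seed, tol = tol, max_iter = max_iter)),
            class = "scca_experiment")
}

#' @export
print.scca_experiment <- function(x, ...) {
  cat(sprintf("<scca_experiment> %d replicate(s), %d failed\n",
              x$config$replicates, length(x$failed)))
  if (nrow(x$tests)) {
    cat("rejection rates (Bonferroni):\n")
    print(dplyr::summarise(dplyr::group_by(x$tests, .data$component),
                           rate = mean(.data$reject_bonferroni)))
  }
  invisible(x)
}
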