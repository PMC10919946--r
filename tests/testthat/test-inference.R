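fake_perm_report <- function(p_raw, observed = seq_along(p_raw),
                             null_draws = NULL, b = 99L) {
  k <- length(p_raw)
  structure(tibble::tibble(
    component = seq_len(k), observed = observed, p_raw = p_raw,
    p_bonferroni = NA_real_, significant_max_stat = NA,
    b = b, statistic = "oos", seed = 1L,
    null_draws = null_draws %||% replicate(k, runif(b), simplify = FALSE)),
    class = c("scca_perm", class(tibble::tibble())))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("permutation p-value convention: +1/+1, floor at 1/(B+1)", {
  expect_equal(softcca:::perm_pvalue(0.9, rep(0.1, 99)), 0.01)
  expect_equal(softcca:::perm_pvalue(-5, rep(0.1, 99)), 1)
  expect_equal(softcca:::perm_pvalue(0.1, rep(0.1, 99)), 1)  # ties count as >=
  expect_gte(softcca:::perm_pvalue(Inf, runif(19)), 1 / 20)
})

test_that("Bonferroni arithmetic with the min(1, .) cap", {
  rep3 <- fake_perm_report(c(0.005, 0.03, 0.4))
  out <- adjust_multiplicity(rep3, "bonferroni")
  expect_equal(out$p_bonferroni, c(0.015, 0.09, 1))
  # K = 1: unchanged
  rep1 <- fake_perm_report(0.02)
  expect_equal(adjust_multiplicity(rep1, "bonferroni")$p_bonferroni, 0.02)
})

test_that("max-statistic rule thresholds on the strongest component's null", {
  nulls <- list(seq(0, 0.98, length.out = 50), seq(0, 0.98, length.out = 50))
  # both observed below the 95th percentile of the reference null
  lo <- fake_perm_report(c(0.5, 0.5), observed = c(0.2, 0.1), null_draws = nulls,
                         b = 50L)
  out <- adjust_multiplicity(lo, "max_stat", alpha = 0.05)
  expect_false(any(out$significant_max_stat))
  # first observed clears the threshold, second does not
  hi <- fake_perm_report(c(0.01, 0.5), observed = c(0.99, 0.1),
                         null_draws = nulls, b = 50L)
  out2 <- adjust_multiplicity(hi, "max_stat", alpha = 0.05)
  expect_true(out2$significant_max_stat[1])
  expect_false(out2$significant_max_stat[2])
})

test_that("a clear signal yields the exact permutation floor and seed-stable reports", {
  sp <- signal_pair(n = 60, p = 60, q = 30, k_true = 1, s1 = 15, s2 = 10,
                    latent_sd = 3, seed = 5)
  pt <- scca_perm_test(sp$pair, 15, 10, k = 1, b = 99, statistic = "oos",
                       folds = 4, seed = 9)
  expect_equal(pt$p_raw, 1 / 100)
  expect_equal(pt$p_bonferroni, pt$p_raw)  # single component
  pt2 <- scca_perm_test(sp$pair, 15, 10, k = 1, b = 99, statistic = "oos",
                        folds = 4, seed = 9)
  expect_identical(serialize(tidy(pt), NULL), serialize(tidy(pt2), NULL))
})

test_that("null draws and observed use the same sparsity and routine", {
  pr <- noise_pair(n = 30, p = 20, q = 15, seed = 6)
  pt <- scca_perm_test(pr, 5, 4, k = 1, b = 19, statistic = "insample",
                       folds = 3, seed = 2)
  expect_length(pt$null_draws[[1]], 19)
  # in-sample statistics live in [0, 1] here and p respects the floor
  expect_true(all(pt$null_draws[[1]] >= -1 & pt$null_draws[[1]] <= 1))
  expect_gte(pt$p_raw, 1 / 20)
  expect_error(scca_perm_test(pr, 5, 4, k = 1, b = 5, seed = 1), "b")
})

test_that("permutation p-values are valid under the null", {
  # small Monte-Carlo check of super-uniformity at alpha = 0.2
  set.seed(7)
  rej <- vapply(1:30, function(r) {
    s <- scca_simulate(scca_design(n = 30, p = 30, q = 20, k_true = 0,
                                   seed = 3000 + r))
    p <- scca_standardize(s$x1, s$x2)
    pt <- scca_perm_test(p, 5, 4, k = 1, b = 19, statistic = "oos",
                         folds = 3, seed = r)
    pt$p_raw <= 0.2
  }, logical(1))
  # binomial(30, 0.2): P(X > 13) < 1e-3
  expect_lte(sum(rej), 13)
})
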