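test_that("a one-component fit equals a single component on the raw pair", {
  sp <- signal_pair(seed = 6)
  fit <- scca_fit(sp$pair, 20, 12, k = 1, seed = 2)
  comp <- scca_component(sp$pair, 20, 12, seed = 2)
  expect_equal(fit$alpha[, 1], comp$alpha, ignore_attr = TRUE)
  expect_equal(fit$beta[, 1], comp$beta, ignore_attr = TRUE)
  expect_equal(fit$rho[1], comp$rho_insample)
})

test_that("deflation makes unpenalized latent variables orthogonal", {
  pair <- noise_pair(n = 30, p = 10, q = 8, seed = 12)
  fit <- scca_fit(pair, 10, 8, k = 2, seed = 1, tol = 1e-12, max_iter = 10000)
  g1 <- fit$components[[1]]$gamma
  g2 <- fit$components[[2]]$gamma
  expect_lt(abs(sum(g1 * g2)), 1e-8)
  z1 <- fit$components[[1]]$zeta
  z2 <- fit$components[[2]]$zeta
  expect_lt(abs(sum(z1 * z2)), 1e-8)
})

test_that("fits are bitwise reproducible under a seed", {
  sp <- signal_pair(seed = 3)
  f1 <- scca_fit(sp$pair, 25, 15, k = 2, seed = 7, folds = 4)
  f2 <- scca_fit(sp$pair, 25, 15, k = 2, seed = 7, folds = 4)
  expect_identical(serialize(f1, NULL), serialize(f2, NULL))
  f3 <- scca_fit(sp$pair, 25, 15, k = 2, seed = 8)
  expect_false(identical(f3$alpha, f1$alpha))
})

test_that("explained variance is monotone and the adjustment only discounts", {
  sp <- signal_pair(seed = 10)
  fit <- scca_fit(sp$pair, 25, 15, k = 3, seed = 1)
  for (ev in list(fit$ev_1, fit$ev_2)) {
    expect_true(all(diff(ev$cpev) >= -1e-12))
    expect_true(all(ev$cpev_adj <= ev$cpev + 1e-12))
    expect_true(all(ev$cpev_adj >= -1e-12))
    expect_true(all(ev$cpev <= 1 + 1e-12))
  }
})

test_that("out-of-sample correlations are attached per component when folds given", {
  sp <- signal_pair(seed = 5)
  fit <- scca_fit(sp$pair, 20, 12, k = 2, seed = 4, folds = 4)
  expect_length(fit$rho_oos, 2)
  expect_true(all(is.finite(fit$rho_oos)))
  expect_equal(fit$components[[1]]$rho_oos, fit$rho_oos[1])
})

test_that("degenerate later components truncate the fit with a warning", {
  # block 2 holds one clean variable plus an exactly duplicated pair:
  # component 1 picks the clean variable; after deflation only the tied
  # duplicates remain and q_beta = 1 shrinks the survivor to zero
  set.seed(21)
  v <- rnorm(30)
  w <- rnorm(30)
  x2 <- cbind(v, w, w)
  x1 <- matrix(rnorm(30 * 6), 30)
  x1[, 1] <- v + 0.01 * rnorm(30)
  pair <- scca_standardize(x1, x2)
  expect_warning(fit <- scca_fit(pair, 3, 1, k = 3, seed = 1), "degenerate")
  expect_lt(fit$k, 3)
  expect_identical(fit$k, length(fit$components))
})

test_that("the sparsity path reproduces standalone fits and preserves lockstep equality", {
  sp <- signal_pair(seed = 4)
  grid <- c(10, 20, 40)
  path <- scca_path(sp$pair, p_alpha = grid, q_beta = 12, k = 2, seed = 5)
  # single-level path is exactly a fit
  single <- scca_path(sp$pair, p_alpha = 20, q_beta = 12, k = 2, seed = 5)
  ref <- scca_fit(sp$pair, 20, 12, k = 2, seed = 5)
  expect_equal(single$fits[[1]]$alpha, ref$alpha, tolerance = 1e-12)
  # lockstep vs independent fits, same seed: entrywise within 1e-10
  for (l in seq_along(grid)) {
    f <- scca_fit(sp$pair, grid[l], 12, k = 2, seed = 5)
    expect_equal(path$fits[[l]]$alpha, f$alpha, tolerance = 1e-10)
    expect_equal(path$fits[[l]]$beta, f$beta, tolerance = 1e-10)
    expect_equal(path$fits[[l]]$rho, f$rho, tolerance = 1e-10)
  }
})

test_that("supports are nested along the sparsity grid under strong signal", {
  sp <- signal_pair(seed = 2)
  path <- scca_path(sp$pair, p_alpha = c(5, 10, 20, 40), q_beta = 12,
                    k = 2, seed = 3)
  nest <- support_nested(path)
  expect_true(all(nest$nested))
})

test_that("tidy, glance and component summaries are consistent with the fit", {
  sp <- signal_pair(seed = 7)
  fit <- scca_fit(sp$pair, 20, 12, k = 2, seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(dplyr::filter(td, dataset == "x1", component == 1)), 20)
  expect_equal(nrow(dplyr::filter(td, dataset == "x2", component == 2)), 12)
  gl <- glance(fit)
  expect_identical(gl$k, 2L)
  expect_equal(gl$rho_1, fit$rho[1])
  tab <- scca_components(fit)
  expect_equal(tab$nnz_alpha, c(20L, 20L))
  expect_equal(tab$cpev_adj_1, fit$ev_1$cpev_adj)
  # plots build without evaluation errors
  expect_s3_class(ggplot2::autoplot(fit, "weights"), "ggplot")
  expect_s3_class(ggplot2::autoplot(fit, "cpev"), "ggplot")
})
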