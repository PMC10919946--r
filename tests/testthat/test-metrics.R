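make_pair_from <- function(x1, x2) {
  # pair-like container for metric tests on hand-built centered matrices
  structure(list(x1 = x1, x2 = x2,
                 sample_ids = sprintf("S%d", seq_len(nrow(x1))),
                 feature_names_1 = sprintf("a%d", seq_len(ncol(x1))),
                 feature_names_2 = sprintf("b%d", seq_len(ncol(x2)))),
            class = "scca_pair")
}

test_that("canonical correlation: self, orthogonal and hand-computed cases", {
  # identical latents
  set.seed(1)
  x <- matrix(rnorm(20 * 5), 20)
  pr <- scca_standardize(x, x)
  a <- runif(5)
  expect_equal(canonical_cor(a, a, pr), 1, tolerance = 1e-12)
  # orthogonal latents: u, v centered with <u, v> = 0
  u <- rep(c(1, -1), 4)
  v <- rep(c(1, 1, -1, -1), 2)
  pr2 <- make_pair_from(cbind(u), cbind(v))
  expect_equal(canonical_cor(1, 1, pr2), 0, tolerance = 1e-12)
  # hand instance: latents (1,2,3,4) and (1,1,2,2) centered;
  # cor = 2 / sqrt(5 * 1)
  a4 <- c(1, 2, 3, 4) - 2.5
  b4 <- c(1, 1, 2, 2) - 1.5
  pr3 <- make_pair_from(cbind(a4), cbind(b4))
  expect_equal(canonical_cor(1, 1, pr3), 2 / sqrt(5), tolerance = 1e-12)
  # zero projection errors
  expect_error(canonical_cor(0, 1, pr3), "zero norm")
})

test_that("cpev: trivial and direct-formula cases", {
  set.seed(2)
  # a single variable explains itself
  x <- matrix(rnorm(10), 10, 1)
  expect_equal(cpev(x, x), 1)
  # zero latents explain nothing
  expect_equal(cpev(matrix(0, 10, 3), x), c(0, 0, 0))
  # direct trace computation
  xx <- matrix(rnorm(40), 10, 4)
  g <- matrix(rnorm(30), 10, 3)
  ref <- sapply(1:3, function(k) {
    gk <- g[, 1:k, drop = FALSE]
    sum(diag(crossprod(gk))) / sum(diag(crossprod(xx)))
  })
  expect_equal(cpev(g, xx), ref, tolerance = 1e-12)
  expect_error(cpev(matrix(0, 9, 2), xx), "rows")
})

test_that("adjusted CPEV: uncorrelated, duplicated, and exact product cases", {
  n <- 6
  u <- orthonormal_centered(n, 4)
  # orthogonal latents: no discount
  ev <- cpev_adjusted(c(0.2, 0.3, 0.4), u[, 1:3])
  expect_equal(ev$cpev_adj, ev$cpev)
  # duplicated latent: second increment fully discounted
  ev2 <- cpev_adjusted(c(0.2, 0.4), cbind(u[, 1], u[, 1]))
  expect_equal(ev2$cpev_adj[2], 0)
  # pairwise |cor| exactly 0.5 via l_i = u0 + u_i: adj[3] = cpev[3] * 0.25
  l <- cbind(u[, 1] + u[, 2], u[, 1] + u[, 3], u[, 1] + u[, 4])
  ev3 <- cpev_adjusted(c(0.2, 0.3, 0.4), l)
  expect_equal(ev3$cross_component_cor[1, 2], 0.5, tolerance = 1e-12)
  expect_equal(ev3$cpev_adj[3], 0.4 * 0.25, tolerance = 1e-12)
  # first component is never discounted
  expect_equal(ev3$cpev_adj[1], 0.2)
})

test_that("adjusted CPEV is invariant to latent sign flips", {
  set.seed(3)
  g <- matrix(rnorm(40), 10, 4)
  cp <- cpev(g, matrix(rnorm(100), 10))
  e1 <- cpev_adjusted(cp, g)
  flip <- g %*% diag(c(1, -1, 1, -1))
  e2 <- cpev_adjusted(cp, flip)
  expect_equal(e1$cpev_adj, e2$cpev_adj, tolerance = 1e-12)
})

test_that("out-of-sample correlation is near zero for independent blocks", {
  set.seed(4)
  ms <- vapply(1:50, function(r) {
    s <- scca_simulate(scca_design(n = 40, p = 15, q = 10, k_true = 0,
                                   seed = 1000 + r))
    p <- scca_standardize(s$x1, s$x2)
    scca_oos(p, 5, 4, folds = 4, seed = r)$mean_oos
  }, numeric(1))
  expect_lt(abs(mean(ms)), 0.1)
})

test_that("out-of-sample correlation sees planted signal but not in-sample optimism", {
  s <- scca_simulate(scca_design(n = 100, p = 300, q = 100, k_true = 1,
                                 support_sizes_1 = 20, support_sizes_2 = 15,
                                 latent_sd = 1.2, seed = 2))
  p <- scca_standardize(s$x1, s$x2)
  fit <- scca_fit(p, 100, 40, k = 1, seed = 3, folds = 5)
  expect_gt(fit$rho_oos[1], 0.3)      # well above the noise level
  expect_lt(fit$rho_oos[1], fit$rho[1])  # in-sample estimate is optimistic
})

test_that("degenerate fold layouts are rejected", {
  pr <- noise_pair(n = 10, p = 6, q = 5, seed = 5)
  expect_error(scca_oos(pr, 3, 3, folds = 10, seed = 1), "folds")
  expect_error(scca_oos(pr, 3, 3, folds = 1, seed = 1), "folds")
})

test_that("oos mean is the mean of the fold correlations", {
  sp <- signal_pair(seed = 8)
  o <- scca_oos(sp$pair, 20, 12, folds = 4, seed = 2)
  expect_equal(o$mean_oos, mean(o$fold_correlations))
  expect_length(o$fold_correlations, 4)
})
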