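test_that("design validation enforces the generative invariants", {
  expect_error(scca_design(p = 50, support_sizes_1 = c(30, 30),
                           support_sizes_2 = c(10, 5), k_true = 2,
                           latent_sd = c(2, 1)), "exceed p")
  expect_error(scca_design(k_true = 2, support_sizes_1 = c(10, 5),
                           support_sizes_2 = c(5, 5), latent_sd = c(1, 2)),
               "decreasing")
  expect_error(scca_design(k_true = 1, support_sizes_1 = 10,
                           support_sizes_2 = 5, latent_sd = c(1, 2)),
               "length k_true")
  expect_error(scca_design(k_true = 0, noise_sd = 0), "nothing to generate")
})

test_that("generation is seed-deterministic and seeds differ", {
  d <- scca_design(n = 20, p = 30, q = 15, k_true = 1, support_sizes_1 = 5,
                   support_sizes_2 = 4, latent_sd = 2, seed = 11)
  s1 <- scca_simulate(d)
  s2 <- scca_simulate(d)
  expect_identical(s1$x1, s2$x1)
  expect_identical(s1$truth$latent_draws, s2$truth$latent_draws)
  d2 <- d; d2$seed <- 12L
  expect_false(identical(scca_simulate(d2)$x1, s1$x1))
})

test_that("a noiseless single factor gives rank-1 blocks with perfectly tied latents", {
  d <- scca_design(n = 25, p = 12, q = 8, k_true = 1, support_sizes_1 = 6,
                   support_sizes_2 = 4, latent_sd = 2, noise_sd = 0, seed = 5)
  s <- scca_simulate(d)
  expect_equal(qr(s$x1)$rank, 1L)
  expect_equal(qr(s$x2)$rank, 1L)
  u <- drop(s$x1 %*% s$truth$true_loadings_1[[1]])
  v <- drop(s$x2 %*% s$truth$true_loadings_2[[1]])
  expect_equal(abs(cor(u, v)), 1, tolerance = 1e-12)
})

test_that("loadings are nonzero exactly on disjoint supports", {
  s <- scca_simulate(scca_design(n = 10, p = 60, q = 40, k_true = 3,
                                 support_sizes_1 = c(10, 8, 5),
                                 support_sizes_2 = c(6, 5, 4),
                                 latent_sd = c(3, 2, 1), seed = 2))
  for (kk in 1:3) {
    expect_identical(which(s$truth$true_loadings_1[[kk]] != 0),
                     s$truth$true_supports_1[[kk]])
  }
  all1 <- unlist(s$truth$true_supports_1)
  expect_identical(anyDuplicated(all1), 0L)
})

test_that("sample covariance matches the implied factor covariance", {
  # implied cov(X1) = W diag(sd^2) W' + noise^2 I; average sample covs
  # over seeds and compare in relative Frobenius norm
  d0 <- scca_design(n = 400, p = 12, q = 8, k_true = 2,
                    support_sizes_1 = c(4, 3), support_sizes_2 = c(3, 2),
                    latent_sd = c(2, 1.5), noise_sd = 1, seed = 1)
  acc <- matrix(0, 12, 12)
  wref <- NULL
  for (r in 1:10) {
    d <- d0; d$seed <- 100L + r
    s <- scca_simulate(d)
    acc <- acc + cov(s$x1)
    w <- do.call(cbind, s$truth$true_loadings_1)
    implied <- w %*% diag(c(2, 1.5)^2) %*% t(w) + diag(12)
    wref <- if (is.null(wref)) implied / 10 else wref + implied / 10
  }
  acc <- acc / 10
  expect_lt(norm(acc - wref, "F") / norm(wref, "F"), 0.1)
})

test_that("recovery scoring: exact, disjoint and oversized-support cases", {
  sp <- signal_pair(n = 100, p = 80, q = 50, k_true = 1, s1 = 12, s2 = 8,
                    latent_sd = 3, seed = 9)
  # fit at the true support size: perfect support recovery expected at
  # this signal strength
  fit <- scca_fit(sp$pair, 12, 8, k = 1, seed = 1)
  sc <- scca_score(fit, sp$sim$truth)
  expect_equal(sc$precision_1, 1)
  expect_equal(sc$recall_1, 1)
  expect_equal(sc$f1_1, 1)
  expect_gt(sc$cosine_1, 0.95)
  expect_equal(sc$contamination_1, 0)
  # oversized support: recall stays 1, the top-s F1 still identifies the
  # true variables as the heaviest
  fit2 <- scca_fit(sp$pair, 40, 20, k = 1, seed = 1)
  sc2 <- scca_score(fit2, sp$sim$truth)
  expect_equal(sc2$recall_1, 1)
  expect_equal(sc2$f1_top_1, 1)
  expect_lt(sc2$precision_1, 1)
  # a deliberately off-support weight vector scores zero
  bad <- fit
  a <- numeric(80); a[70:80] <- 1
  bad$alpha[, 1] <- a / sqrt(sum(a^2))
  bad$latents_1 <- sp$pair$x1 %*% bad$alpha
  sc3 <- scca_score(bad, sp$sim$truth)
  expect_equal(sc3$precision_1, 0)
  expect_equal(sc3$f1_1, 0)
})

test_that("the experiment harness is deterministic and tabulates all stages", {
  d <- scca_design(n = 40, p = 30, q = 20, k_true = 1, support_sizes_1 = 6,
                   support_sizes_2 = 5, latent_sd = 3, seed = 1)
  e1 <- suppressWarnings(
    scca_experiment(d, p_alpha = 6, q_beta = 5, k = 1, replicates = 2,
                    b = 19, folds = 4, grid_p_alpha = c(4, 8), seed = 3))
  e2 <- suppressWarnings(
    scca_experiment(d, p_alpha = 6, q_beta = 5, k = 1, replicates = 2,
                    b = 19, folds = 4, grid_p_alpha = c(4, 8), seed = 3))
  expect_identical(serialize(e1$tests, NULL), serialize(e2$tests, NULL))
  expect_identical(serialize(e1$recovery, NULL), serialize(e2$recovery, NULL))
  expect_equal(nrow(e1$explained), 2)
  expect_equal(nrow(e1$nestedness), 2)
  expect_true(all(c("p_raw", "reject_bonferroni") %in% names(e1$tests)))
})

test_that("planted components are recovered across seeds at the reference design", {
  # operationalizes "consistently selects the corresponding variables":
  # top-s weights (s = true support size) recover each planted support
  f1s <- sapply(1:20, function(r) {
    sim <- scca_simulate(scca_design(seed = 400 + r))
    pair <- scca_standardize(sim$x1, sim$x2)
    fit <- scca_fit(pair, 100, 100, k = 3, seed = r)
    sc <- scca_score(fit, sim$truth)
    c(sc$f1_top_1, sc$f1_top_2)
  })
  expect_gt(mean(f1s), 0.9)
  expect_true(all(rowMeans(matrix(f1s, nrow = 6)) > 0.9))
})
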