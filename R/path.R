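#' Fit several sparsity levels in one NIPALS run
#'
#' Estimates the model at every requested `(p_alpha, q_beta)` pair
#' simultaneously: all levels share one initialization and are updated in
#' lockstep as columns of latent-variable matrices, with each column
#' soft-thresholded at its own support size and its convergence tracked
#' independently. The per-level results are identical to calling
#' [scca_fit()] separately at each level with the same seed; the lockstep
#' form exists to make browsing a sparsity grid cheap.
#'
#' @param pair an [scca_pair][scca_standardize].
#' @param p_alpha,q_beta vectors of target nonzero counts; recycled to a
#'   common length, one fit per element.
#' @inheritParams scca_fit
#' @return an `scca_path`: list with `fits` (one `scca_fit` per level) and
#'   the level table. See [support_nested()].
#' @export
scca_path <- function(pair, p_alpha, q_beta, k = 1L,
                      init = "uniform_random", seed = 1L,
                      tol = 1e-6, max_iter = 500L,
                      cpev_convention = c("weights_unit", "latents_unit")) {
  stopifnot(inherits(pair, "scca_pair"))
  cpev_convention <- match.arg(cpev_convention)
  if (length(p_alpha) == 0L) stop("need at least one sparsity level", call. = FALSE)
  L <- max(length(p_alpha), length(q_beta))
  pa <- as.integer(rep_len(p_alpha, L))
  qb <- as.integer(rep_len(q_beta, L))
  p <- ncol(pair$x1); q <- ncol(pair$x2)
  k <- assert_count(k, "k")
  if (k > min(p, q)) stop("k must not exceed min(p, q)", call. = FALSE)
  init <- match.arg(init, c("uniform_random", "uniform_constant",
                            "decomposition"))
  inits <- draw_inits(p, k, init, seed)

  x1d <- replicate(L, pair$x1, simplify = FALSE)
  x2d <- replicate(L, pair$x2, simplify = FALSE)
  comps <- replicate(L, list(), simplify = FALSE)
  alive <- rep(TRUE, L)

  for (kk in seq_len(k)) {
    act <- which(alive)
    if (!length(act)) break
    if (kk == 1L) {
      iv <- if (identical(init, "decomposition")) decomposition_init(pair$x1) else inits[[1L]]
      res_act <- nipals_path_component(pair$x1, pair$x2, pa[act], qb[act],
                                       iv, tol, max_iter)
    } else {
      res_act <- lapply(act, function(l) {
        iv <- if (identical(init, "decomposition")) decomposition_init(x1d[[l]]) else inits[[kk]]
        nipals_fit(x1d[[l]], x2d[[l]], pa[l], qb[l], iv,
                   tol = tol, max_iter = max_iter)
      })
    }
    for (j in seq_along(act)) {
      l <- act[j]
      f <- res_act[[j]]
      if (f$degenerate) {
        warning(sprintf("level %d (p_alpha = %d): component %d degenerate; truncating",
                        l, pa[l], kk), call. = FALSE)
        alive[l] <- FALSE
        next
      }
      if (f$tie_alpha || f$tie_beta) {
        warning(sprintf("level %d, component %d: tie at the threshold boundary", l, kk),
                call. = FALSE)
      }
      comps[[l]] <- c(comps[[l]], list(f))
      if (kk < k) {
        x1d[[l]] <- deflate_latent(x1d[[l]], f$gamma)
        x2d[[l]] <- deflate_latent(x2d[[l]], f$zeta)
      }
    }
  }

  fits <- lapply(seq_len(L), function(l) {
    if (length(comps[[l]]) == 0L) return(NULL)
    assemble_fit(pair, comps[[l]], p_alpha = pa[l], q_beta = qb[l],
                 k_requested = k, init = init, seed = seed, tol = tol,
                 max_iter = as.integer(max_iter),
                 cpev_convention = cpev_convention)
  })
  structure(list(fits = fits,
                 levels = tibble::tibble(level = seq_len(L),
                                         p_alpha = pa, q_beta = qb)),
            class = "scca_path")
}

# Lockstep update of one component across L sparsity levels sharing the
# same input matrices and initialization. Columns are independent, so
# freezing a converged column reproduces the standalone fit exactly.
nipals_path_component <- function(x1, x2, pa, qb, init, tol, max_iter) {
  L <- length(pa)
  n <- nrow(x1); p <- ncol(x1); q <- ncol(x2)
  empty <- function() list(alpha = numeric(p), beta = numeric(q),
                           gamma = numeric(n), zeta = numeric(n),
                           rho_insample = NA_real_, n_iter = 0L,
                           converged = FALSE, degenerate = TRUE,
                           tie_alpha = FALSE, tie_beta = FALSE,
                           rho_trace = numeric(0))
  gamma0 <- unit_norm(drop(x1 %*% init))
  if (all(gamma0 == 0)) return(replicate(L, empty(), simplify = FALSE))

  Gamma <- matrix(gamma0, n, L)
  Alpha <- matrix(0, p, L); Beta <- matrix(0, q, L); Zeta <- matrix(0, n, L)
  active <- rep(TRUE, L)
  deg <- conv <- rep(FALSE, L)
  tie_a <- tie_b <- rep(FALSE, L)
  iters <- integer(L)
  rho_prev <- numeric(L)
  traces <- replicate(L, numeric(0), simplify = FALSE)

  t <- 0L
  while (any(active) && t < max_iter) {
    t <- t + 1L
    act <- which(active)
    Bt <- crossprod(x2, Gamma[, act, drop = FALSE])
    for (j in seq_along(act)) {
      l <- act[j]
      bth <- soft_threshold_k(Bt[, j], qb[l])
      tie_b[l] <- tie_b[l] || attr(bth, "tied")
      Beta[, l] <- as.numeric(bth)
      if (all(Beta[, l] == 0)) {
        deg[l] <- TRUE; active[l] <- FALSE; iters[l] <- t
      }
    }
    act <- which(active)
    if (!length(act)) break
    Zt <- x2 %*% Beta[, act, drop = FALSE]
    for (j in seq_along(act)) Zeta[, act[j]] <- unit_norm(Zt[, j])
    At <- crossprod(x1, Zeta[, act, drop = FALSE])
    for (j in seq_along(act)) {
      l <- act[j]
      ath <- soft_threshold_k(At[, j], pa[l])
      tie_a[l] <- tie_a[l] || attr(ath, "tied")
      Alpha[, l] <- as.numeric(ath)
      if (all(Alpha[, l] == 0)) {
        deg[l] <- TRUE; active[l] <- FALSE; iters[l] <- t
      }
    }
    act <- which(active)
    if (!length(act)) break
    Gt <- x1 %*% Alpha[, act, drop = FALSE]
    for (j in seq_along(act)) {
      l <- act[j]
      Gamma[, l] <- unit_norm(Gt[, j])
      rho <- safe_cor(Gamma[, l], Zeta[, l])
      if (is.na(rho)) {
        deg[l] <- TRUE; active[l] <- FALSE; iters[l] <- t
        next
      }
      traces[[l]] <- c(traces[[l]], rho)
      if (abs(rho - rho_prev[l]) <= tol) {
        conv[l] <- TRUE; active[l] <- FALSE; iters[l] <- t
      } else {
        rho_prev[l] <- rho
      }
    }
  }
  iters[active] <- t  # hit max_iter

  lapply(seq_len(L), function(l) {
    if (deg[l]) {
      out <- empty()
      out$n_iter <- iters[l]
      out$tie_alpha <- tie_a[l]; out$tie_beta <- tie_b[l]
      out$rho_trace <- traces[[l]]
      return(out)
    }
    alpha <- Alpha[, l]; beta <- Beta[, l]
    s <- sign(alpha[which.max(abs(alpha))]); if (s == 0) s <- 1
    gamma <- s * Gamma[, l]; zeta <- s * Zeta[, l]
    list(alpha = unit_norm(s * alpha), beta = unit_norm(s * beta),
         gamma = gamma, zeta = zeta,
         rho_insample = safe_cor(gamma, zeta),
         n_iter = iters[l], converged = conv[l], degenerate = FALSE,
         tie_alpha = tie_a[l], tie_beta = tie_b[l],
         rho_trace = traces[[l]])
  })
}

#' @export
print.scca_path <- function(x, ...) {
  cat(sprintf("<scca_path> %d sparsity level(s)\n", nrow(x$levels)))
  print(x$levels)
  invisible(x)
}

#' Check support nestedness along a sparsity path
#'
#' With a genuine signal, the nonzero set chosen at a small support size
#' should be contained in the one chosen at any larger size (with the
#' other block's sparsity fixed). Returns, per component, whether the
#' block-1 supports are nested along increasing `p_alpha`.
#'
#' @param path an [scca_path()] result.
#' @return tibble with columns `component` and `nested`.
#' @export
support_nested <- function(path) {
  stopifnot(inherits(path, "scca_path"))
  ord <- order(path$levels$p_alpha)
  fits <- path$fits[ord]
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) < 2L) {
    return(tibble::tibble(component = integer(0), nested = logical(0)))
  }
  k <- min(vapply(fits, function(f) f$k, integer(1)))
  tibble::tibble(
    component = seq_len(k),
    nested = vapply(seq_len(k), function(kk) {
      supports <- lapply(fits, function(f) which(f$alpha[, kk] != 0))
      all(vapply(seq_len(length(supports) - 1L), function(i) {
        all(supports[[i]] %in% supports[[i + 1L]])
      }, logical(1)))
    }, logical(1))
  )
}
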