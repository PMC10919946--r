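#' Rank-based soft-thresholding with an exact target support size
#'
#' Keeps the `keep` largest entries of `v` by absolute value, shrinks each
#' survivor towards zero by the magnitude of the first excluded entry, and
#' zeroes the rest. Signs are preserved. This is the sparsity primitive of
#' the whole package: instead of tuning a penalty parameter, the caller
#' states the number of nonzero weights directly.
#'
#' The shrinkage constant is \eqn{\lambda = |v|_{(keep+1)}}, the
#' (`keep`+1)-th largest magnitude (\eqn{\lambda = 0} when `keep` equals
#' `length(v)` or when fewer than `keep + 1` entries are nonzero). Entries
#' tied in magnitude at the boundary are admitted in ascending index order
#' until `keep` entries are selected; a survivor whose magnitude equals
#' \eqn{\lambda} shrinks to exactly zero, so the result can have fewer than
#' `keep` nonzeros. Callers inspect the `"tied"` attribute to report this.
#'
#' @param v numeric vector.
#' @param keep integer, `1 <= keep <= length(v)`: target number of nonzeros.
#' @return numeric vector of the same length, with at most `keep` nonzero
#'   entries; attributes `"lambda"` (the shrinkage used) and `"tied"`
#'   (`TRUE` when a boundary tie shrank a survivor to zero).
#' @examples
#' soft_threshold_k(c(3, -2, 1, 0), 2)  # (2, -1, 0, 0)
#' @export
soft_threshold_k <- function(v, keep) {
  m <- length(v)
  keep <- assert_count(keep, "keep")
  if (keep > m) stop("`keep` must not exceed length(v)", call. = FALSE)
  a <- abs(v)
  w <- numeric(m)
  if (all(a == 0)) {
    attr(w, "lambda") <- 0
    attr(w, "tied") <- FALSE
    return(w)
  }
  if (keep == m) {
    lambda <- 0
    surv <- seq_len(m)
    tied <- FALSE
  } else {
    # lambda = (keep+1)-th largest magnitude, via partial sort
    lambda <- sort(a, partial = m - keep)[m - keep]
    surv <- which(a > lambda)
    need <- keep - length(surv)
    tied <- need > 0L && lambda > 0
    if (need > 0L) {
      # boundary ties admitted in ascending index order; they shrink to 0
      surv <- c(surv, which(a == lambda)[seq_len(need)])
    }
  }
  w[surv] <- sign(v[surv]) * (a[surv] - lambda)
  attr(w, "lambda") <- lambda
  attr(w, "tied") <- tied
  w
}
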