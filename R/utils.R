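#' @importFrom rlang %||% abort warn .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom stats dnorm rnorm optim setNames approx
NULL

# Cholesky with escalating diagonal jitter.
# Starts at 1e-10 * mean(diag), escalates x10 up to 1e-6 * mean(diag),
# then fails with an error naming the offending block.
chol_with_jitter <- function(M, what = "covariance") {
  n <- nrow(M)
  if (n == 0L) return(list(L = M, jitter = 0))
  scale <- mean(diag(M))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  jit <- 1e-10 * scale
  max_jit <- 1e-6 * scale
  repeat {
    L <- tryCatch(chol(M + diag(jit, n)), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = jit))
    if (jit >= max_jit) {
      abort(sprintf(
        "numerical conditioning failure in the %s block: Cholesky failed even with jitter %.3g",
        what, jit))
    }
    jit <- jit * 10
  }
}

# Solve M x = b through an existing upper-triangular Cholesky factor.
chol_solve <- function(L, b) {
  backsolve(L, forwardsolve(t(L), b))
}

# Moore-Penrose pseudoinverse via SVD (used only for the optional
# minimum-norm flux solution).
pseudo_inverse <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive per-stage seeds from one top-level seed.
split_seed <- function(seed, n) {
  with_local_seed(seed, sample.int(.Machine$integer.max, n))
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}
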