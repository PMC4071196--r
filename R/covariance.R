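#' Assemble the joint covariance over observations, functions and derivatives
#'
#' Builds the block covariance matrix of the dependent GP model at a set of
#' observation times and (optionally) test times. Rows/columns are ordered as:
#' observed function values per output (model output order, time-sorted
#' within), then latent function values at test times per output, then
#' derivative values at test times per output. Observation noise
#' \eqn{\sigma_i^2} enters the diagonal of the observed block only; a small
#' jitter (starting at `1e-10 * mean(diag)` and escalating tenfold up to
#' `1e-6 * mean(diag)` before failing) keeps the observed block positive
#' definite.
#'
#' @param spec An [mgp_spec()].
#' @param params An [mgp_params()] vector.
#' @param obs_times Named list (by output) of observation time vectors;
#'   outputs may be missing or empty.
#' @param test_times Named list (by output) of test time vectors, or a single
#'   numeric vector used for every output, or `NULL` for likelihood-only use.
#' @return An object of class `covariance_blocks` with components
#'   `CC` (function-point covariance, observations first), `DC`
#'   (derivative-by-function cross block, `cov(U(t_test), Y(t))`), `DDC`
#'   (derivative covariance), `noise_diag` (per function point; zero at test
#'   points), the assembled symmetric matrix `K`, the observed block `K_obs`
#'   (noise and jitter included), the cross block `K_cross` between
#'   observations and all test quantities, the test-quantity block `K_test`,
#'   index tibbles `f_index`, `d_index`, `test_index`, the observation count
#'   `n_obs` and the `jitter` used.
#' @export
build_joint_covariance <- function(spec, params, obs_times, test_times = NULL) {
  assert_that(inherits(spec, "mgp_spec"), "`spec` must be an mgp_spec")
  assert_that(inherits(params, "mgp_params"), "`params` must be an mgp_params")
  assert_that(all(is.finite(params$theta)), "hyperparameters must be finite")

  norm_times <- function(x) {
    if (is.null(x)) x <- list()
    if (is.numeric(x)) x <- setNames(rep(list(x), spec$K), spec$outputs)
    assert_that(is.list(x) && (length(x) == 0L || !is.null(names(x))),
                "time sets must be a named list or a numeric vector")
    unknown <- setdiff(names(x), spec$outputs)
    assert_that(length(unknown) == 0L,
                paste0("times given for unknown outputs: ",
                       paste(unknown, collapse = ", ")))
    out <- lapply(spec$outputs, function(o) as.numeric(x[[o]] %||% numeric(0)))
    names(out) <- spec$outputs
    assert_that(all(vapply(out, function(v) all(is.finite(v)), TRUE)),
                "times must be finite")
    out
  }
  obs_times <- norm_times(obs_times)
  test_times <- norm_times(test_times)

  kerns <- lapply(spec$outputs, function(o) kernels_for_output(spec, params, o))
  names(kerns) <- spec$outputs
  sigma <- noise_sd(spec, params)

  f_index <- tibble::tibble(
    output = rep(c(rep(spec$outputs, lengths(obs_times)),
                   rep(spec$outputs, lengths(test_times))), times = 1),
    time = c(unlist(obs_times, use.names = FALSE),
             unlist(test_times, use.names = FALSE)),
    role = rep(c("obs", "test"), c(sum(lengths(obs_times)),
                                   sum(lengths(test_times))))
  )
  d_index <- tibble::tibble(
    output = rep(spec$outputs, lengths(test_times)),
    time = unlist(test_times, use.names = FALSE)
  )
  n_obs <- sum(lengths(obs_times))
  n_f <- nrow(f_index)
  n_d <- nrow(d_index)

  fill <- function(index_i, index_j, type) {
    M <- matrix(0, nrow(index_i), nrow(index_j))
    for (oi in spec$outputs) {
      ri <- which(index_i$output == oi)
      if (!length(ri)) next
      for (oj in spec$outputs) {
        rj <- which(index_j$output == oj)
        if (!length(rj)) next
        M[ri, rj] <- block_cov(kerns[[oi]], kerns[[oj]],
                               index_i$time[ri], index_j$time[rj], type)
      }
    }
    M
  }

  CC <- fill(f_index, f_index, "yy")
  CC <- (CC + t(CC)) / 2
  DC <- fill(d_index, f_index, "uy")
  DDC <- fill(d_index, d_index, "uu")
  DDC <- (DDC + t(DDC)) / 2

  noise_diag <- numeric(n_f)
  if (n_obs > 0L) {
    noise_diag[seq_len(n_obs)] <- (sigma[f_index$output[seq_len(n_obs)]])^2
  }

  jitter <- 0
  K_obs <- matrix(0, 0, 0)
  if (n_obs > 0L) {
    K_obs <- CC[seq_len(n_obs), seq_len(n_obs), drop = FALSE] +
      diag(noise_diag[seq_len(n_obs)], n_obs)
    ch <- chol_with_jitter(K_obs, "observation")
    jitter <- ch$jitter
    K_obs <- K_obs + diag(jitter, n_obs)
  }

  K <- rbind(cbind(CC + diag(noise_diag, n_f), t(DC)),
             cbind(DC, DDC))
  if (nrow(K) > 0L) K <- K + diag(jitter, nrow(K))
  K <- (K + t(K)) / 2

  # test-quantity view: latent functions at test points, then derivatives
  t_rows <- which(f_index$role == "test")
  K_cross <- cbind(CC[seq_len(n_obs), t_rows, drop = FALSE],
                   t(DC[, seq_len(n_obs), drop = FALSE]))
  K_test <- rbind(
    cbind(CC[t_rows, t_rows, drop = FALSE],
          t(DC[, t_rows, drop = FALSE])),
    cbind(DC[, t_rows, drop = FALSE], DDC)
  )
  K_test <- (K_test + t(K_test)) / 2
  test_index <- tibble::tibble(
    output = c(f_index$output[t_rows], d_index$output),
    time = c(f_index$time[t_rows], d_index$time),
    quantity = rep(c("function", "derivative"), c(length(t_rows), n_d))
  )

  structure(
    list(CC = CC, DC = DC, DDC = DDC, noise_diag = noise_diag,
         K = K, K_obs = K_obs, K_cross = K_cross, K_test = K_test,
         f_index = f_index, d_index = d_index, test_index = test_index,
         n_obs = n_obs, jitter = jitter, sigma = sigma),
    class = "covariance_blocks"
  )
}

# Precompiled builder for the observation-block covariance: the pairing
# structure (which kernel pairs share a source, per output pair) and the
# outer time-difference matrices depend only on the spec and the observation
# times, so they are computed once; evaluating the covariance for a new
# hyperparameter vector is then pure vectorized arithmetic. Used in the MAP
# objective, where the covariance is rebuilt thousands of times.
obs_cov_builder <- function(spec, obs_times) {
  K <- spec$K
  ne <- nrow(spec$edges)
  n_i <- lengths(obs_times)
  n <- sum(n_i)
  offset <- cumsum(c(0, n_i))[seq_len(K)]
  out_rows <- rep(seq_len(K), n_i)
  blocks <- list()
  for (i in seq_len(K)) {
    ei <- which(spec$edges$output == spec$outputs[i])
    for (j in seq_len(i)) {
      if (n_i[i] == 0L || n_i[j] == 0L) next
      ej <- which(spec$edges$output == spec$outputs[j])
      pair <- expand.grid(h = ei, g = ej)
      pair <- pair[spec$edges$source[pair$h] == spec$edges$source[pair$g], ,
                   drop = FALSE]
      if (!nrow(pair)) next
      D2 <- outer(obs_times[[i]], obs_times[[j]], "-")^2
      blocks[[length(blocks) + 1L]] <- list(
        i = i, j = j, h = pair$h, g = pair$g, D2 = D2,
        rows = offset[i] + seq_len(n_i[i]), cols = offset[j] + seq_len(n_i[j]))
    }
  }
  function(theta) {
    A <- exp(theta[seq_len(ne)])
    b <- exp(theta[ne + seq_len(ne)])
    s2 <- exp(2 * theta[2L * ne + out_rows])
    M <- diag(s2, n)
    for (bl in blocks) {
      bsum <- b[bl$h] + b[bl$g]
      sig <- b[bl$h] * b[bl$g] / bsum
      pref <- A[bl$h] * A[bl$g] * sqrt(2 * pi / bsum)
      B <- 0
      for (m in seq_along(sig)) B <- B + pref[m] * exp(-0.5 * sig[m] * bl$D2)
      M[bl$rows, bl$cols] <- M[bl$rows, bl$cols] + B
      if (bl$i != bl$j) M[bl$cols, bl$rows] <- M[bl$cols, bl$rows] + t(B)
    }
    M
  }
}

# Fast Gaussian log-density given a prebuilt observation covariance.
lml_from_K <- function(y, K_obs) {
  ch <- chol_with_jitter(K_obs, "observation")
  alpha <- chol_solve(ch$L, y)
  as.numeric(-0.5 * sum(y * alpha) - sum(log(diag(ch$L))) -
               0.5 * length(y) * log(2 * pi))
}

#' @export
print.covariance_blocks <- function(x, ...) {
  cat("<covariance_blocks> ", x$n_obs, " observations, ",
      nrow(x$test_index), " test quantities, jitter ",
      format(x$jitter, digits = 3), "\n", sep = "")
  invisible(x)
}
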