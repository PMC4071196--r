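# Independent oracles, deliberately written as plain scalar loops so they
# share no code path with the package implementation.

# Scalar convolution covariance between outputs i and j at separation d,
# summing over kernel pairs that share a source.
naive_cov_yy <- function(ki, kj, d) {
  total <- 0
  for (h in seq_len(nrow(ki))) {
    for (g in seq_len(nrow(kj))) {
      if (ki$source[h] != kj$source[g]) next
      bh <- ki$inv_width[h]; bg <- kj$inv_width[g]
      sig <- bh * bg / (bh + bg)
      total <- total + ki$amplitude[h] * kj$amplitude[g] *
        sqrt(2 * pi / (bh + bg)) * exp(-0.5 * sig * d^2)
    }
  }
  total
}

# Numerical quadrature of the defining convolution integral
# int h_i(t - s) h_j(t' - s) ds with d = t - t'.
quadrature_cov_yy <- function(ki, kj, d) {
  total <- 0
  for (h in seq_len(nrow(ki))) {
    for (g in seq_len(nrow(kj))) {
      if (ki$source[h] != kj$source[g]) next
      Ah <- ki$amplitude[h]; bh <- ki$inv_width[h]
      Ag <- kj$amplitude[g]; bg <- kj$inv_width[g]
      total <- total + stats::integrate(
        function(s) Ah * exp(-bh * (d - s)^2 / 2) * Ag * exp(-bg * s^2 / 2),
        -Inf, Inf, rel.tol = 1e-12)$value
    }
  }
  total
}

# Full joint covariance over (observations, test functions, test derivatives)
# built entrywise from the scalar covariance functions; noise on the observed
# diagonal. Row order matches build_joint_covariance.
naive_joint_cov <- function(spec, params, obs, test_times, jitter = NULL) {
  kerns <- lapply(spec$outputs, function(o)
    fluxgp:::kernels_for_output(spec, params, o))
  names(kerns) <- spec$outputs
  sigma <- fluxgp:::noise_sd(spec, params)
  if (is.numeric(test_times)) {
    test_times <- stats::setNames(rep(list(test_times), spec$K), spec$outputs)
  }
  pts <- rbind(
    data.frame(output = obs$output, time = obs$time, q = "obs"),
    do.call(rbind, lapply(spec$outputs, function(o)
      if (length(test_times[[o]]))
        data.frame(output = o, time = test_times[[o]], q = "fun") else NULL)),
    do.call(rbind, lapply(spec$outputs, function(o)
      if (length(test_times[[o]]))
        data.frame(output = o, time = test_times[[o]], q = "der") else NULL))
  )
  n <- nrow(pts)
  M <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      ka <- kerns[[pts$output[a]]]; kb <- kerns[[pts$output[b]]]
      d <- pts$time[a] - pts$time[b]
      da <- pts$q[a] == "der"; db <- pts$q[b] == "der"
      M[a, b] <- if (!da && !db) {
        naive_cov_yy(ka, kb, d)
      } else if (da && !db) {
        cov_uy(ka, kb, d)
      } else if (!da && db) {
        -cov_uy(ka, kb, d)
      } else {
        cov_uu(ka, kb, d)
      }
      if (a == b && pts$q[a] == "obs") {
        M[a, b] <- M[a, b] + sigma[[pts$output[a]]]^2
      }
    }
  }
  # the model adds a deterministic diagonal jitter to the observed block;
  # include the same quantum so the oracle evaluates the same covariance
  if (is.null(jitter)) {
    obs_times <- split(obs$time, factor(obs$output, levels = spec$outputs))
    jitter <- build_joint_covariance(spec, params, obs_times)$jitter
  }
  o <- which(pts$q == "obs")
  M[cbind(o, o)] <- M[cbind(o, o)] + jitter
  list(M = M, pts = pts)
}

# Brute-force Gaussian conditioning of a joint zero-mean normal on the first
# block, via plain solve().
naive_condition <- function(M, y, obs_idx) {
  test_idx <- setdiff(seq_len(nrow(M)), obs_idx)
  S11 <- M[obs_idx, obs_idx, drop = FALSE]
  S12 <- M[obs_idx, test_idx, drop = FALSE]
  S22 <- M[test_idx, test_idx, drop = FALSE]
  mu <- as.numeric(t(S12) %*% solve(S11, y))
  Sg <- S22 - t(S12) %*% solve(S11, S12)
  list(mean = mu, cov = (Sg + t(Sg)) / 2)
}

# Ordered observation table matching the package's canonical row order.
ordered_obs <- function(data, spec) {
  data[order(match(data$output, spec$outputs), data$time), , drop = FALSE]
}

random_kernel_pair <- function() {
  list(
    ki = kernel_spec(stats::runif(1, 0.3, 2), stats::runif(1, 0.1, 3), "s"),
    kj = kernel_spec(stats::runif(1, 0.3, 2), stats::runif(1, 0.1, 3), "s")
  )
}
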