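test_that("closed-form covariance matches its defining convolution integral", {
  k <- kernel_spec(1, 1)
  expect_equal(cov_yy(k, k, 0), sqrt(pi), tolerance = 1e-12)

  ki <- kernel_spec(1.3, 2.0)
  kj <- kernel_spec(0.7, 0.5)
  q <- quadrature_cov_yy(ki, kj, 0.8)
  expect_lt(abs(cov_yy(ki, kj, 0.8) - q) / q, 1e-6)

  withr::with_seed(31, {
    for (r in 1:20) {
      p <- random_kernel_pair()
      d <- stats::runif(1, -2, 2)
      q <- quadrature_cov_yy(p$ki, p$kj, d)
      expect_lt(abs(cov_yy(p$ki, p$kj, d) - q) / abs(q), 1e-6)
    }
  })
})

test_that("autocovariance is even and cross-derivative covariance is odd in d", {
  k <- rbind(kernel_spec(0.8, 0.6, "a"), kernel_spec(1.4, 2.2, "b"))
  d <- seq(-3, 3, by = 0.37)
  expect_equal(cov_yy(k, k, d), cov_yy(k, k, -d))
  expect_equal(cov_uy(k, k, d), -cov_uy(k, k, -d))
  expect_equal(cov_uy(k, k, 0), 0)
  expect_gt(cov_uu(k, k, 0), 0)
})

test_that("derivative covariances agree with finite differences of cov_yy", {
  withr::with_seed(17, {
    for (r in 1:200) {
      p <- random_kernel_pair()
      d <- stats::runif(1, -2, 2)
      eps <- 1e-5
      fd1 <- (cov_yy(p$ki, p$kj, d + eps) - cov_yy(p$ki, p$kj, d - eps)) /
        (2 * eps)
      expect_lt(abs(cov_uy(p$ki, p$kj, d) - fd1), 1e-5)
      eps2 <- 1e-4
      fd2 <- -(cov_yy(p$ki, p$kj, d + eps2) - 2 * cov_yy(p$ki, p$kj, d) +
                 cov_yy(p$ki, p$kj, d - eps2)) / eps2^2
      expect_lt(abs(cov_uu(p$ki, p$kj, d) - fd2),
                1e-4 * max(1, abs(fd2)))
    }
  })
  # exact value at zero separation: sig = 1/2, cov_yy(0) = sqrt(pi)
  k <- kernel_spec(1, 1)
  expect_equal(cov_uu(k, k, 0), sqrt(pi) / 2, tolerance = 1e-12)
})

test_that("outputs without a shared source are independent", {
  ki <- kernel_spec(1, 1, "s1", "y1")
  kj <- kernel_spec(1, 1, "s2", "y2")
  expect_identical(cov_yy(ki, kj, 0.5), 0)
  spec <- mgp_spec(c("y1", "y2"),
                   data.frame(source = c("s1", "s2"),
                              output = c("y1", "y2")))
  cb <- build_joint_covariance(spec, mgp_params(spec),
                               obs_times = list(y1 = 0:3, y2 = 0:3))
  expect_true(all(cb$CC[1:4, 5:8] == 0))
})

test_that("duplicate (source, output) kernels are rejected", {
  k2 <- rbind(kernel_spec(1, 1, "s", "y"), kernel_spec(2, 1, "s", "y"))
  expect_error(cov_yy(k2, k2, 0), "duplicate")
  expect_error(kernel_spec(-1, 1), "positive")
  expect_error(kernel_spec(1, 0), "positive")
})

test_that("single-output model reduces to a squared exponential plus noise", {
  spec <- mgp_spec("y", data.frame(source = "s", output = "y"))
  A <- 1.7; b <- 0.9; s <- 0.23
  params <- mgp_params(spec, log(A), log(b), log(s))
  tt <- seq(0, 5, length.out = 12)
  cb <- build_joint_covariance(spec, params, obs_times = list(y = tt))
  se_var <- A^2 * sqrt(pi / b)
  SE <- se_var * exp(-0.25 * b * outer(tt, tt, "-")^2) + diag(s^2, 12)
  expect_lt(max(abs(cb$K_obs - diag(cb$jitter, 12) - SE)), 1e-12)
})

test_that("assembled joint covariance is symmetric and positive semidefinite", {
  spec <- two_output_spec()
  withr::with_seed(5, {
    for (r in 1:20) {
      params <- mgp_params(spec, stats::rnorm(4), stats::rnorm(4),
                           stats::rnorm(2, -1))
      cb <- build_joint_covariance(
        spec, params,
        obs_times = list(y1 = sort(stats::runif(6, 0, 5)),
                         y2 = sort(stats::runif(4, 0, 5))),
        test_times = seq(0, 5, length.out = 4))
      expect_identical(cb$K, t(cb$K))
      ev <- eigen(cb$K, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-8 * max(ev))
      # spec-declared block layout: K = [[CC + noise, DC'], [DC, DDC]]
      nf <- nrow(cb$f_index)
      expect_equal(cb$K[seq_len(nf), -seq_len(nf)], t(cb$DC))
    }
  })
})

test_that("empirical covariance of prior draws matches K (sampling consistency)", {
  spec <- mgp_spec("y", data.frame(source = "s", output = "y"))
  params <- mgp_params(spec, log(0.8), log(1.2), log(0.05))
  grid <- seq(0, 2, length.out = 5)
  cb <- build_joint_covariance(spec, params,
                               obs_times = list(y = numeric(0)),
                               test_times = list(y = grid))
  K <- cb$K_test[1:5, 1:5]
  n <- 20000
  withr::with_seed(77, {
    L <- chol(K + diag(1e-12, 5))
    Z <- matrix(stats::rnorm(n * 5), n) %*% L
  })
  emp <- crossprod(Z) / n
  mc_se <- sqrt((outer(diag(K), diag(K)) + K^2) / n)
  expect_true(all(abs(emp - K) <= 3 * mc_se))
})

test_that("non-finite hyperparameters and non-PSD matrices are rejected", {
  spec <- mgp_spec("y", data.frame(source = "s", output = "y"))
  params <- mgp_params(spec)
  params$theta[1] <- NaN
  expect_error(build_joint_covariance(spec, params, list(y = 0:2)), "finite")
  M <- diag(2); M[1, 2] <- M[2, 1] <- 2   # indefinite
  expect_error(fluxgp:::chol_with_jitter(M, "observation"),
               "conditioning failure in the observation block")
})
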