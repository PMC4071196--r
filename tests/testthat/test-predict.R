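make_fixture <- function(seed = 8, n1 = 6, n2 = 5) {
  spec <- two_output_spec()
  withr::with_seed(seed, {
    params <- mgp_params(spec, stats::rnorm(4, 0, 0.4),
                         stats::rnorm(4, 0, 0.4), log(0.15))
    data <- tibble::tibble(
      output = rep(c("y1", "y2"), c(n1, n2)),
      time = c(sort(stats::runif(n1, 0, 5)), sort(stats::runif(n2, 0, 5))),
      value = stats::rnorm(n1 + n2)
    )
  })
  list(spec = spec, params = params, data = data)
}

test_that("posterior equals brute-force conditioning of the joint normal", {
  for (seed in c(8, 15, 23)) {
    fx <- make_fixture(seed)
    grid <- seq(0.3, 4.7, length.out = 7)
    pred <- posterior_joint(fx$data, fx$spec, fx$params, grid)
    ord <- ordered_obs(fx$data, fx$spec)
    nj <- naive_joint_cov(fx$spec, fx$params, ord, grid)
    oracle <- naive_condition(nj$M, ord$value, seq_len(nrow(ord)))
    expect_lt(max(abs(pred$mean - oracle$mean)), 1e-8)
    expect_lt(max(abs(attr(pred, "covariance") - oracle$cov)), 1e-8)
    # row labelling agrees with the naive construction
    test_pts <- nj$pts[nj$pts$q != "obs", ]
    expect_equal(attr(pred, "index")$output, test_pts$output)
    expect_equal(attr(pred, "index")$time, test_pts$time)
  }
})

test_that("with no observations the prior is returned", {
  fx <- make_fixture()
  empty <- fx$data[0, ]
  grid <- seq(0, 5, length.out = 5)
  pred <- posterior_joint(empty, fx$spec, fx$params, grid)
  expect_true(all(pred$mean == 0))
  cb <- build_joint_covariance(fx$spec, fx$params,
                               obs_times = list(), test_times = grid)
  expect_equal(pred$sd, sqrt(diag(cb$K_test)))
})

test_that("marginal prediction equals the joint diagonal", {
  fx <- make_fixture(42)
  grid <- seq(0.5, 4.5, length.out = 6)
  joint <- posterior_joint(fx$data, fx$spec, fx$params, grid)
  for (o in c("y1", "y2")) {
    marg <- posterior_marginal(fx$data, fx$spec, fx$params, grid, o)
    jo <- tidy(joint)[tidy(joint)$output == o, ]
    expect_equal(marg$mean, jo$mean, tolerance = 1e-12)
    expect_equal(marg$sd, jo$sd, tolerance = 1e-12)
  }
  expect_error(posterior_marginal(fx$data, fx$spec, fx$params, grid, "zz"),
               "unknown output")
})

test_that("a near-noiseless observation is interpolated almost exactly", {
  spec <- mgp_spec("y", data.frame(source = "s", output = "y"))
  params <- mgp_params(spec, log(1), log(1), log(1e-8))
  data <- tibble::tibble(output = "y", time = c(1, 2, 3),
                         value = c(0.5, -0.2, 0.7))
  pred <- posterior_joint(data, spec, params, c(2, 2.5))
  f <- tidy(pred)[tidy(pred)$quantity == "function", ]
  expect_lt(abs(f$mean[f$time == 2] - (-0.2)), 1e-6)
  prior_var <- cov_yy(kernel_spec(1, 1), kernel_spec(1, 1), 0)
  expect_lt(f$sd[f$time == 2]^2, 1e-8 * prior_var)
})

test_that("derivative posterior mean is the derivative of the function mean", {
  fx <- make_fixture(3)
  grid <- seq(0.5, 4.5, length.out = 401)
  pred <- tidy(posterior_joint(fx$data, fx$spec, fx$params, grid))
  h <- grid[2] - grid[1]
  for (o in c("y1", "y2")) {
    f <- pred$mean[pred$output == o & pred$quantity == "function"]
    u <- pred$mean[pred$output == o & pred$quantity == "derivative"]
    interior <- 2:(length(grid) - 1)
    fd <- (f[interior + 1] - f[interior - 1]) / (2 * h)
    expect_lt(max(abs(u[interior] - fd)) / max(abs(fd)), 1e-3)
  }
})

test_that("adding an observation never increases function predictive variance", {
  fx <- make_fixture(19)
  grid <- seq(0, 5, length.out = 11)
  base <- tidy(posterior_joint(fx$data[-1, ], fx$spec, fx$params, grid))
  full <- tidy(posterior_joint(fx$data, fx$spec, fx$params, grid))
  f <- base$quantity == "function"
  expect_true(all(full$sd[f] <= base$sd[f] + 1e-10))
})

test_that("include_noise widens only the function bands", {
  fx <- make_fixture(11)
  grid <- seq(0, 5, length.out = 6)
  latent <- tidy(posterior_joint(fx$data, fx$spec, fx$params, grid))
  noisy <- tidy(posterior_joint(fx$data, fx$spec, fx$params, grid,
                                include_noise = TRUE))
  s2 <- fluxgp:::noise_sd(fx$spec, fx$params)^2
  f <- latent$quantity == "function"
  expect_equal(noisy$sd[f]^2, latent$sd[f]^2 + unname(s2[latent$output[f]]))
  expect_equal(noisy$sd[!f], latent$sd[!f])
})

test_that("joint posterior samples reproduce the posterior moments", {
  fx <- make_fixture(29)
  grid <- seq(1, 4, length.out = 4)
  pred <- posterior_joint(fx$data, fx$spec, fx$params, grid)
  draws <- posterior_samples(pred, n = 4000, seed = 1)
  emp <- tapply(draws$value,
                paste(draws$output, draws$time, draws$quantity), mean)
  key <- paste(pred$output, pred$time, pred$quantity)
  mc_se <- pred$sd / sqrt(4000)
  expect_true(all(abs(emp[key] - pred$mean) <= 4 * mc_se + 1e-8))
  d2 <- posterior_samples(pred, n = 5, seed = 2)
  d3 <- posterior_samples(pred, n = 5, seed = 2)
  expect_identical(d2, d3)
})
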