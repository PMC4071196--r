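test_that("flux estimability is classified from the reduced system rank", {
  # branched pathway over the measured metabolites: 4 fluxes, 2 equations
  st <- stoichiometry(rbind(x2 = c(0, 1, -1, 0), x3 = c(0, 0, 1, 0)),
                      fluxes = c("v1", "v2", "v3", "v4"))
  cls <- classify_fluxes(st)
  expect_equal(cls$status[cls$flux %in% c("v2", "v3")],
               c("estimable", "estimable"))
  expect_equal(cls$status[cls$flux %in% c("v1", "v4")],
               c("underdetermined", "underdetermined"))
  expect_equal(attr(cls, "system"), "underdetermined")
  # the chain differences: v2 = dx2 + dx3, v3 = dx3
  co <- attr(cls, "coefficients")
  expect_equal(unname(co$v2), c(1, 1))
  expect_equal(unname(co$v3), c(0, 1))

  # linear pathway: declaring the efflux known makes v1, v2 estimable
  st2 <- stoichiometry(rbind(x2 = c(1, -1, 0), x3 = c(0, 1, -1)),
                       fluxes = c("v1", "v2", "v3"),
                       known = list(v3 = function(t) 0 * t + 0.4))
  cls2 <- classify_fluxes(st2)
  expect_equal(cls2$status, c("estimable", "estimable", "known"))

  # one flux per metabolite: everything estimable
  st3 <- stoichiometry(diag(3))
  expect_true(all(classify_fluxes(st3)$status == "estimable"))
})

# A prediction object with a controlled derivative covariance, built from a
# real posterior on a fixture model.
flux_fixture <- function(seed = 14) {
  spec <- two_output_spec(c("x2", "x3"))
  withr::with_seed(seed, {
    params <- mgp_params(spec, stats::rnorm(4, 0, 0.3),
                         stats::rnorm(4, 0, 0.3), log(0.1))
    data <- tibble::tibble(
      output = rep(c("x2", "x3"), each = 6),
      time = rep(seq(0, 5, length.out = 6), 2),
      value = stats::rnorm(12)
    )
  })
  grid <- seq(0.5, 4.5, length.out = 9)
  list(pred = posterior_joint(data, spec, params, grid), grid = grid)
}

test_that("an identity system returns the derivative posterior verbatim", {
  fx <- flux_fixture()
  st <- stoichiometry(rbind(x2 = 1), fluxes = "v")
  fl <- tidy(estimate_fluxes(fx$pred, st))
  d <- tidy(fx$pred)
  d <- d[d$output == "x2" & d$quantity == "derivative", ]
  expect_equal(fl$mean, d$mean)
  expect_equal(fl$sd, d$sd)
})

test_that("flux variance respects the derivative cross-covariance", {
  fx <- flux_fixture()
  # dx2 = v + u, dx3 = u  =>  v = dx2/dt - dx3/dt, u = dx3/dt,
  # so var(v) = s2^2 + s3^2 - 2 cov(d2, d3)
  st <- stoichiometry(rbind(x2 = c(1, 1), x3 = c(0, 1)),
                      fluxes = c("v", "u"))
  fl <- tidy(estimate_fluxes(fx$pred, st))
  v <- fl[fl$flux == "v", ]
  idx <- attr(fx$pred, "index")
  Sigma <- attr(fx$pred, "covariance")
  r2 <- which(idx$output == "x2" & idx$quantity == "derivative")
  r3 <- which(idx$output == "x3" & idx$quantity == "derivative")
  for (k in seq_along(fx$grid)) {
    expect_equal(v$sd[k]^2,
                 Sigma[r2[k], r2[k]] + Sigma[r3[k], r3[k]] -
                   2 * Sigma[r2[k], r3[k]],
                 tolerance = 1e-10)
  }
})

test_that("analytic flux sd matches the sd of propagated posterior samples", {
  fx <- flux_fixture(30)
  st <- stoichiometry(rbind(x2 = c(0, 1, -1, 0), x3 = c(0, 0, 1, 0)),
                      fluxes = c("v1", "v2", "v3", "v4"))
  fl <- tidy(estimate_fluxes(fx$pred, st))
  draws <- posterior_samples(fx$pred, n = 10000, seed = 99)
  d2 <- draws[draws$output == "x2" & draws$quantity == "derivative", ]
  d3 <- draws[draws$output == "x3" & draws$quantity == "derivative", ]
  # v2 = dx2 + dx3 per draw; rows align by construction within draws
  stopifnot(identical(d2$.draw, d3$.draw), identical(d2$time, d3$time))
  v2_draws <- d2$value + d3$value
  for (tk in unique(d2$time)[c(2, 5, 8)]) {
    emp_sd <- stats::sd(v2_draws[d2$time == tk])
    ana_sd <- fl$sd[fl$flux == "v2" & fl$time == tk]
    expect_lt(abs(emp_sd - ana_sd) / ana_sd, 0.05)
  }
})

test_that("a closed stoichiometric loop is consistent with zero net flux", {
  fx <- flux_fixture(55)
  # net-zero combination of derivatives: (dx2 - dx2) must be 0 exactly;
  # expressed as a loop flux through S with cancelling coefficients
  st <- stoichiometry(rbind(x2 = c(1, -1), x3 = c(1, -1)),
                      fluxes = c("f", "g"),
                      known = list(g = function(t) 0 * t))
  # reduced system: dx2 = f, dx3 = f -> overdetermined; consistency requires
  # dx2 approx dx3, which a generic posterior violates beyond uncertainty
  # only if the check is broken. Here we test the exact-conservation case:
  pred <- fx$pred
  idx <- attr(pred, "index")
  r2 <- which(idx$output == "x2" & idx$quantity == "derivative")
  r3 <- which(idx$output == "x3" & idx$quantity == "derivative")
  pred$mean[r3] <- pred$mean[r2]   # enforce the conserved geometry
  Sig <- attr(pred, "covariance")
  Sig[r3, ] <- Sig[r2, ]; Sig[, r3] <- Sig[, r2]
  attr(pred, "covariance") <- Sig
  fl <- estimate_fluxes(pred, st)
  # the implied loop residual dx2 - dx3 has mean 0 and variance 0
  expect_equal(pred$mean[r2] - pred$mean[r3], rep(0, length(r2)))
  expect_lt(max(abs(Sig[r2, r2] + Sig[r3, r3] - Sig[r2, r3] - Sig[r3, r2])),
            1e-10)
  expect_true(all(tidy(fl)$status %in% c("estimable", "known")))
})

test_that("inconsistent known-flux substitution in an overdetermined system errors", {
  fx <- flux_fixture(41)
  st <- stoichiometry(rbind(x2 = 1, x3 = 1), fluxes = "f")
  # dx2 = f and dx3 = f, but the posterior derivatives of x2 and x3 differ
  # by far more than their joint uncertainty after shifting x2's mean
  pred <- fx$pred
  idx <- attr(pred, "index")
  r2 <- idx$output == "x2" & idx$quantity == "derivative"
  pred$mean[r2] <- pred$mean[r2] + 100
  expect_error(estimate_fluxes(pred, st), "inconsistent known-flux")
})

test_that("minimum-norm trajectories are opt-in and warn", {
  fx <- flux_fixture(62)
  st <- stoichiometry(rbind(x2 = c(0, 1, -1, 0), x3 = c(0, 0, 1, 0)),
                      fluxes = c("v1", "v2", "v3", "v4"))
  fl <- estimate_fluxes(fx$pred, st)
  expect_false(any(tidy(fl)$flux %in% c("v1", "v4")))
  expect_warning(fl2 <- estimate_fluxes(fx$pred, st, min_norm = TRUE),
                 "minimum-norm")
  expect_true(all(c("v1", "v4") %in% tidy(fl2)$flux))
  expect_true(all(tidy(fl2)$status[tidy(fl2)$flux == "v1"] == "minimum_norm"))
})

test_that("tabulated known fluxes require grid agreement unless interpolation is enabled", {
  fx <- flux_fixture(70)
  tab <- data.frame(time = c(0, 10), value = c(0.3, 0.3))
  st <- stoichiometry(rbind(x2 = c(1, -1)),
                      fluxes = c("v1", "v2"),
                      known = list(v2 = tab))
  expect_error(estimate_fluxes(fx$pred, st), "interpolate_known")
  fl <- tidy(estimate_fluxes(fx$pred, st, interpolate_known = TRUE))
  expect_equal(unique(fl$mean[fl$flux == "v2"]), 0.3)
})
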