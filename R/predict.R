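#' Joint posterior over functions and derivatives at test points
#'
#' Conditions the joint zero-mean Gaussian prior over (observations, latent
#' function values, derivative values) on the observed data. With `K_obs` the
#' observed-block covariance (noise included), `H` the cross block and
#' `K_test` the test-quantity block, the posterior is Gaussian with mean
#' \eqn{H^T K_{obs}^{-1} y} and covariance
#' \eqn{K_{test} - H^T K_{obs}^{-1} H}. Because the derivative of a
#' convolution-constructed GP is again a GP driven by the same white noise,
#' functions and derivatives are predicted jointly and coherently.
#'
#' Reported variances are for the latent function (no observation noise), so
#' credible bands are smooth curves through the noisy data; set
#' `include_noise = TRUE` for data-space bands on the function rows.
#'
#' @param data Long-format observations (`output`, `time`, `value`); may have
#'   zero rows, in which case the prior is returned.
#' @param spec An [mgp_spec()].
#' @param params An [mgp_params()] vector (typically a fitted one).
#' @param times Test times: numeric vector (used for every output) or named
#'   list per output.
#' @param include_noise Add \eqn{\sigma_i^2} to the function-value variances.
#' @param centers Optional named per-output constants added back to function
#'   means (used when the data were centred before fitting).
#' @return An object of class `mgp_prediction`: a tibble with columns
#'   `output`, `time`, `quantity` (`"function"` or `"derivative"`), `mean`,
#'   `sd`, carrying the full joint test covariance in
#'   `attr(, "covariance")` and its index in `attr(, "index")`.
#' @export
posterior_joint <- function(data, spec, params, times,
                            include_noise = FALSE, centers = NULL) {
  data <- as_timeseries(data, spec$outputs)
  data <- order_obs(data, spec)
  obs_times <- split(data$time, factor(data$output, levels = spec$outputs))
  cb <- build_joint_covariance(spec, params, obs_times, test_times = times)
  n_test <- nrow(cb$test_index)
  assert_that(n_test > 0L, "no test times supplied")

  if (cb$n_obs == 0L) {
    mean_vec <- rep(0, n_test)
    Sigma <- cb$K_test
  } else {
    L <- chol(cb$K_obs)   # jitter-validated by the assembly step
    alpha <- chol_solve(L, data$value)
    mean_vec <- as.numeric(crossprod(cb$K_cross, alpha))
    W <- chol_solve(L, cb$K_cross)
    Sigma <- cb$K_test - crossprod(cb$K_cross, W)
    Sigma <- (Sigma + t(Sigma)) / 2
  }

  if (isTRUE(include_noise)) {
    f_rows <- which(cb$test_index$quantity == "function")
    s2 <- (cb$sigma[cb$test_index$output[f_rows]])^2
    diag(Sigma)[f_rows] <- diag(Sigma)[f_rows] + s2
  }

  v <- diag(Sigma)
  tol <- 1e-10 * max(1, max(abs(diag(cb$K_test))))
  assert_that(all(v >= -tol),
              sprintf("negative posterior variance beyond round-off (min %.3g); numerical failure",
                      min(v)))
  clip <- v < 0
  v[clip] <- 0
  diag(Sigma)[clip] <- 0

  out <- cb$test_index
  out$mean <- mean_vec
  out$sd <- sqrt(v)
  if (!is.null(centers)) {
    f <- out$quantity == "function"
    add <- centers[out$output[f]]
    add[is.na(add)] <- 0
    out$mean[f] <- out$mean[f] + add
  }
  structure(out,
            covariance = Sigma,
            index = cb$test_index,
            sigma = cb$sigma,
            class = c("mgp_prediction", class(out)))
}

#' Marginal posterior for a single output and its derivative
#'
#' Computes the posterior restricted to one output's test times (still
#' conditioned on all observations of all outputs). The means and variances
#' equal the corresponding entries of [posterior_joint()].
#'
#' @inheritParams posterior_joint
#' @param output The output label to predict.
#' @return An `mgp_prediction` for that output only.
#' @export
posterior_marginal <- function(data, spec, params, times, output,
                               include_noise = FALSE, centers = NULL) {
  assert_that(length(output) == 1L && output %in% spec$outputs,
              paste0("unknown output: ", paste(output, collapse = ", ")))
  if (is.numeric(times)) times <- setNames(list(times), output)
  assert_that(is.list(times) && all(names(times) %in% spec$outputs),
              "`times` must be numeric or a named list")
  times <- times[names(times) == output]
  posterior_joint(data, spec, params, times,
                  include_noise = include_noise, centers = centers)
}

#' Predict from a fitted dependent GP model
#'
#' @param object An [mgp_fit()].
#' @param times Test times (numeric vector or named per-output list); default
#'   is a 101-point grid spanning the observed time range.
#' @param outputs Optional subset of outputs to predict.
#' @param include_noise Add observation-noise variance to function bands.
#' @param ... Unused.
#' @return An `mgp_prediction` (see [posterior_joint()]).
#' @export
predict.mgp_fit <- function(object, times = NULL, outputs = NULL,
                            include_noise = FALSE, ...) {
  if (is.null(times)) {
    r <- range(object$data$time)
    times <- seq(r[1], r[2], length.out = 101)
  }
  if (is.numeric(times)) {
    keep <- outputs %||% object$spec$outputs
    times <- setNames(rep(list(times), length(keep)), keep)
  } else if (!is.null(outputs)) {
    times <- times[names(times) %in% outputs]
  }
  centers <- if (object$centered) object$centers else NULL
  posterior_joint(object$data, object$spec, object$params, times,
                  include_noise = include_noise, centers = centers)
}

#' @export
print.mgp_prediction <- function(x, ...) {
  cat("<mgp_prediction> ", sum(x$quantity == "function"), " function and ",
      sum(x$quantity == "derivative"), " derivative test points\n", sep = "")
  NextMethod()
}

#' Tidy a posterior prediction
#'
#' @param x An `mgp_prediction`.
#' @param ... Unused.
#' @return A plain tibble (`output`, `time`, `quantity`, `mean`, `sd`).
#' @method tidy mgp_prediction
#' @export
tidy.mgp_prediction <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("output", "time", "quantity", "mean", "sd")])
}

#' Draw joint samples from a posterior prediction
#'
#' Samples trajectories of functions and derivatives jointly from the full
#' posterior covariance (not just the marginals), so sampled derivative
#' curves are consistent with the sampled function curves.
#'
#' @param prediction An `mgp_prediction` from [posterior_joint()] or
#'   [predict.mgp_fit()].
#' @param n Number of draws.
#' @param seed Optional seed.
#' @return A tibble with columns `.draw`, `output`, `time`, `quantity`,
#'   `value`.
#' @export
posterior_samples <- function(prediction, n = 100, seed = NULL) {
  Sigma <- attr(prediction, "covariance")
  assert_that(!is.null(Sigma), "prediction carries no joint covariance")
  m <- prediction$mean
  ch <- chol_with_jitter(Sigma, "posterior")
  Z <- with_local_seed(seed, matrix(rnorm(n * length(m)), nrow = n))
  draws <- Z %*% ch$L + matrix(m, n, length(m), byrow = TRUE)
  idx <- attr(prediction, "index")
  tibble::tibble(
    .draw = rep(seq_len(n), each = length(m)),
    output = rep(idx$output, n),
    time = rep(idx$time, n),
    quantity = rep(idx$quantity, n),
    value = as.numeric(t(draws))
  )
}

#' Plot posterior function and derivative bands
#'
#' Mean curves with +/- 2 posterior standard deviation ribbons, faceted by
#' output (columns) and quantity (rows). Observed data points can be overlaid.
#'
#' @param object An `mgp_prediction`.
#' @param data Optional long-format observations to overlay on the function
#'   panels.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mgp_prediction
#' @export
autoplot.mgp_prediction <- function(object, data = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - 2 * .data$sd,
                   ymax = .data$mean + 2 * .data$sd),
      fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "steelblue") +
    ggplot2::facet_grid(quantity ~ output, scales = "free_y") +
    ggplot2::labs(x = "time", y = NULL)
  if (!is.null(data)) {
    pts <- as_timeseries(data)
    pts$quantity <- "function"
    p <- p + ggplot2::geom_point(
      data = pts, ggplot2::aes(x = .data$time, y = .data$value),
      inherit.aes = FALSE, size = 0.9)
  }
  p
}
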