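#' Fit a dependent GP model by multistart MAP estimation
#'
#' Maximizes log marginal likelihood plus log prior over the free (non-fixed)
#' log-scale hyperparameters with a derivative-free Nelder-Mead simplex
#' search, restarted from `n_starts` initial points drawn from the priors.
#' The best terminal point across starts is returned. Reproducible given
#' `seed`.
#'
#' @param data Long-format observations (`output`, `time`, `value`); at least
#'   3 points per modelled output.
#' @param spec An [mgp_spec()].
#' @param priors An [mgp_priors()] table; defaults to `mgp_priors(spec)`.
#' @param n_starts Number of optimizer starts (>= 1).
#' @param seed Integer seed for the start draws.
#' @param fixed Named numeric vector of natural-scale hyperparameter values to
#'   hold constant, named as in [param_names()] but without the `log_` prefix
#'   being applied by the user: names must match [param_names()] and values
#'   are given on the natural (positive) scale, e.g.
#'   `c("log_sigma[y1]" = 0.05)` fixes the noise sd of `y1` at 0.05.
#' @param init Optional [mgp_params()] used as the first start.
#' @param center If `TRUE`, subtract each output's sample mean before fitting
#'   (the GP prior has zero mean); the means are restored at prediction.
#' @param control List with `maxit` (default 2000) and `reltol` (default
#'   1e-8) for [stats::optim()]'s Nelder-Mead.
#' @return An object of class `mgp_fit`.
#' @examples
#' sim <- simulate_oscillators(seed = 1)
#' fit <- mgp_fit(sim$observations, two_output_spec(), n_starts = 2, seed = 1)
#' glance(fit)
#' @export
mgp_fit <- function(data, spec, priors = NULL, n_starts = 10, seed = NULL,
                    fixed = NULL, init = NULL, center = FALSE,
                    control = list()) {
  assert_that(inherits(spec, "mgp_spec"), "`spec` must be an mgp_spec")
  assert_that(is.numeric(n_starts) && n_starts >= 1, "`n_starts` must be >= 1")
  n_starts <- as.integer(n_starts)
  priors <- priors %||% mgp_priors(spec)
  control <- utils::modifyList(list(maxit = 2000, reltol = 1e-8), control)

  data <- as_timeseries(data, spec$outputs, min_points = 3L)
  data <- order_obs(data, spec)

  centers <- setNames(rep(0, spec$K), spec$outputs)
  if (isTRUE(center)) {
    mu <- tapply(data$value, factor(data$output, levels = spec$outputs), mean)
    centers[names(mu)] <- ifelse(is.na(mu), 0, mu)
    data$value <- data$value - centers[data$output]
  }

  fixed_mask <- character()
  base <- mgp_params(spec)
  if (!is.null(fixed)) {
    assert_that(is.numeric(fixed) && !is.null(names(fixed)),
                "`fixed` must be a named numeric vector")
    unknown <- setdiff(names(fixed), names(base$theta))
    assert_that(length(unknown) == 0L,
                paste0("unknown parameter names in `fixed`: ",
                       paste(unknown, collapse = ", ")))
    assert_that(all(fixed > 0),
                "`fixed` values are on the natural scale and must be positive")
    base$theta[names(fixed)] <- log(fixed)
    fixed_mask <- names(fixed)
  }
  base$fixed <- names(base$theta) %in% fixed_mask
  free_names <- names(base$theta)[!base$fixed]
  assert_that(length(free_names) > 0L, "no free parameters to optimize")
  pi_idx <- match(free_names, priors$parameter)
  assert_that(!anyNA(pi_idx), "priors must cover all free parameters")

  obs_times <- split(data$time, factor(data$output, levels = spec$outputs))
  K_of <- obs_cov_builder(spec, obs_times)
  y <- data$value
  objective <- function(free) {
    p <- set_free(base, free)
    tryCatch(
      -(lml_from_K(y, K_of(p$theta)) + log_prior(p, priors)),
      error = function(e) Inf
    )
  }

  starts <- with_local_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      rnorm(length(free_names), priors$location[pi_idx], priors$scale[pi_idx])
    })
  })
  if (!is.null(init)) {
    assert_that(inherits(init, "mgp_params"), "`init` must be an mgp_params")
    starts[[1L]] <- unname(init$theta[free_names])
  }

  runs <- lapply(starts, function(s0) {
    f0 <- objective(s0)
    if (!is.finite(f0)) return(NULL)   # discard start with non-finite objective
    opt <- tryCatch(
      optim(s0, objective, method = "Nelder-Mead",
            control = list(maxit = control$maxit, reltol = control$reltol)),
      error = function(e) NULL
    )
    if (is.null(opt)) return(NULL)
    list(par = opt$par, value = opt$value, start_value = f0,
         convergence = opt$convergence)
  })
  runs <- Filter(Negate(is.null), runs)
  assert_that(length(runs) > 0L,
              "all optimizer starts had non-finite objectives; check data scale and priors")

  values <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(values)]]
  if (best$value >= min(vapply(runs, `[[`, numeric(1), "start_value"))) {
    warn("no optimizer start improved on its initial point; returning the best point seen")
  }

  params <- set_free(base, best$par)
  log_post <- -best$value
  log_lik <- log_marginal_likelihood(data, spec, params)

  structure(
    list(spec = spec, params = params, priors = priors, data = data,
         centers = centers, centered = isTRUE(center),
         log_posterior = log_post, log_lik = log_lik,
         convergence = best$convergence, n_starts = n_starts,
         n_starts_used = length(runs), seed = seed,
         start_values = vapply(runs, `[[`, numeric(1), "value")),
    class = "mgp_fit"
  )
}

#' @export
print.mgp_fit <- function(x, ...) {
  cat("<mgp_fit> ", x$spec$K, " outputs, ", nrow(x$data), " observations\n",
      "  log posterior ", format(x$log_posterior, digits = 6),
      ", log likelihood ", format(x$log_lik, digits = 6), "\n",
      "  ", n_free_params(x$params), " free hyperparameters, ",
      x$n_starts_used, "/", x$n_starts, " starts used\n", sep = "")
  invisible(x)
}

param_type <- function(nm) {
  ifelse(startsWith(nm, "log_A["), "amplitude",
         ifelse(startsWith(nm, "log_b["), "inv_width", "noise_sd"))
}

#' Tidy a fitted dependent GP model
#'
#' @param x An [mgp_fit()] object.
#' @param ... Unused.
#' @return A tibble with one row per hyperparameter: `term`, `type`
#'   (amplitude / inv_width / noise_sd), natural-scale `estimate`,
#'   `log_estimate`, and whether the parameter was `fixed`.
#' @method tidy mgp_fit
#' @export
tidy.mgp_fit <- function(x, ...) {
  th <- x$params$theta
  tibble::tibble(
    term = names(th),
    type = param_type(names(th)),
    estimate = exp(unname(th)),
    log_estimate = unname(th),
    fixed = x$params$fixed
  )
}

#' One-row summary of a fitted dependent GP model
#'
#' @param x An [mgp_fit()] object.
#' @param ... Unused.
#' @return A one-row tibble: `log_posterior`, `log_lik`, `n_obs`,
#'   `n_params_free`, `n_starts`, `convergence`, `seed`.
#' @method glance mgp_fit
#' @export
glance.mgp_fit <- function(x, ...) {
  tibble::tibble(
    log_posterior = x$log_posterior,
    log_lik = x$log_lik,
    n_obs = nrow(x$data),
    n_params_free = n_free_params(x$params),
    n_starts = x$n_starts,
    convergence = x$convergence,
    seed = if (is.null(x$seed)) NA_integer_ else as.integer(x$seed)
  )
}

#' Serialize / restore a fitted model as a structured list
#'
#' `fit_to_list()` captures the model structure, fitted log-scale
#' hyperparameters, priors, objective value and seed in a plain list suitable
#' for [yaml::write_yaml()] or [jsonlite::write_json()]; `fit_from_list()`
#' restores the spec and parameters (not the data).
#'
#' @param fit An [mgp_fit()].
#' @return A plain list.
#' @export
fit_to_list <- function(fit) {
  list(
    outputs = fit$spec$outputs,
    edges = as.list(as.data.frame(fit$spec$edges)),
    theta = as.list(fit$params$theta),
    fixed = names(fit$params$theta)[fit$params$fixed],
    priors = list(parameter = fit$priors$parameter,
                  location = fit$priors$location, scale = fit$priors$scale),
    log_posterior = fit$log_posterior,
    log_lik = fit$log_lik,
    seed = fit$seed,
    centers = as.list(fit$centers),
    package_version = as.character(utils::packageVersion("fluxgp"))
  )
}

#' @rdname fit_to_list
#' @param x A list produced by `fit_to_list()`.
#' @export
fit_from_list <- function(x) {
  spec <- mgp_spec(x$outputs, as.data.frame(x$edges))
  params <- mgp_params(spec)
  theta <- unlist(x$theta)
  params$theta[names(theta)] <- theta
  params$fixed <- names(params$theta) %in% (x$fixed %||% character())
  list(spec = spec, params = params)
}
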