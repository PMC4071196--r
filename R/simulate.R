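#' @title Synthetic time-course generators
#' @description Each generator returns a `flux_simulation`: a dense
#'   ground-truth grid (states, derivatives and fluxes), noisy observations
#'   at the requested sampling times, the observation noise used, and (for
#'   the pathway models) the stoichiometry linking derivatives to fluxes.
#'   Truth derivatives are the ODE right-hand side evaluated on the truth
#'   trajectories, so `dx/dt = S v` holds exactly on every grid point, and
#'   observations are truth plus i.i.d. Gaussian noise reproducible from
#'   `seed`.
#' @name simulators
NULL

new_simulation <- function(truth, fluxes, observations, noise_sd,
                           stoich, seed, params) {
  structure(list(truth = truth, fluxes = fluxes, observations = observations,
                 noise_sd = noise_sd, stoichiometry = stoich, seed = seed,
                 params = params),
            class = "flux_simulation")
}

#' @export
print.flux_simulation <- function(x, ...) {
  outs <- unique(x$truth$output)
  cat("<flux_simulation> outputs {", paste(outs, collapse = ", "), "}, ",
      nrow(x$observations), " observations, noise sd ",
      paste(signif(x$noise_sd, 3), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Plot a simulation: truth, observations and fluxes
#' @param object A `flux_simulation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flux_simulation
#' @export
autoplot.flux_simulation <- function(object, ...) {
  tr <- object$truth
  p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linetype = "dashed") +
    ggplot2::geom_point(data = object$observations, size = 0.9,
                        colour = "firebrick") +
    ggplot2::facet_wrap(~output, scales = "free_y") +
    ggplot2::labs(x = "time", y = "concentration")
  p
}

# Add i.i.d. Gaussian noise to the truth at the observation times.
# noise_sd: named per-output, or NULL for 1% of each output's dynamic range.
sample_observations <- function(truth, observed, obs_times, noise_sd, seed) {
  if (is.numeric(obs_times)) {
    obs_times <- setNames(rep(list(obs_times), length(observed)), observed)
  }
  rng <- vapply(observed, function(o) {
    v <- truth$value[truth$output == o]
    diff(range(v))
  }, numeric(1))
  if (is.null(noise_sd)) noise_sd <- 0.01 * rng
  noise_sd <- setNames(rep_len(noise_sd, length(observed)), observed)
  obs <- with_local_seed(seed, {
    dplyr::bind_rows(lapply(observed, function(o) {
      tt <- as.numeric(obs_times[[o]])
      tv <- truth[truth$output == o, ]
      i <- match(tt, tv$time)
      assert_that(!anyNA(i), "observation times must lie on the truth grid")
      tibble::tibble(output = o, time = tt,
                     value = tv$value[i] + rnorm(length(tt), 0, noise_sd[[o]]))
    }))
  })
  list(observations = obs, noise_sd = noise_sd)
}

# Integrate dx/dt = S_full v(t, x) with a stiff-capable adaptive method and
# tabulate states, derivatives and fluxes on the union of the truth grid and
# the observation times.
integrate_pathway <- function(flux_fn, S_full, init, p, t_max, obs_times,
                              grid_n = 200) {
  assert_that(all(is.finite(init)) && all(init > 0),
              "initial conditions must be positive")
  grid <- seq(0, t_max, length.out = grid_n)
  times <- sort(unique(c(grid, unlist(obs_times))))
  rhs <- function(t, y, parms) {
    v <- flux_fn(t, y, parms)
    list(as.numeric(S_full %*% v))
  }
  sol <- deSolve::ode(y = init, times = times, func = rhs, parms = p,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  assert_that(nrow(sol) == length(times) && all(is.finite(sol)),
              paste0("ODE integration failed: solver returned ",
                     nrow(sol), " of ", length(times),
                     " requested time points or non-finite states"))
  states <- sol[, names(init), drop = FALSE]
  fx <- t(vapply(seq_along(times),
                 function(k) flux_fn(times[k], states[k, ], p),
                 flux_fn(0, init, p)))
  dx <- fx %*% t(S_full)
  truth <- dplyr::bind_rows(lapply(seq_along(names(init)), function(j) {
    tibble::tibble(time = times, output = names(init)[j],
                   value = states[, j], derivative = dx[, j])
  }))
  fluxes <- dplyr::bind_rows(lapply(seq_len(ncol(fx)), function(j) {
    tibble::tibble(time = times, flux = colnames(fx)[j], value = fx[, j])
  }))
  list(truth = truth, fluxes = fluxes, times = times)
}

#' Two noisy oscillating signals with analytic derivatives
#'
#' Generates `A_i sin(w_i t + phi_i)` for two signals, with exact derivative
#' truth `A_i w_i cos(w_i t + phi_i)` and i.i.d. Gaussian observation noise.
#' The default configuration is two unit-amplitude, unit-frequency signals a
#' third of a period out of phase, sampled at 30 regular times over two
#' periods with noise sd equal to 5% of the amplitude.
#'
#' @param amplitudes,angular_freqs,phases Length-2 numeric parameters of the
#'   two sinusoids.
#' @param noise_sd Observation noise sd per signal; default 5% of each
#'   amplitude.
#' @param obs_times Sampling times: numeric vector shared by both signals or
#'   a named list (irregular and unequal sampling is fine).
#' @param t_max,grid_n Truth grid extent and resolution.
#' @param seed Integer seed for the noise draws.
#' @return A `flux_simulation` (no stoichiometry; oscillators have no fluxes).
#' @export
simulate_oscillators <- function(amplitudes = c(1, 1),
                                 angular_freqs = c(1, 1),
                                 phases = c(0, pi / 3),
                                 noise_sd = NULL,
                                 obs_times = seq(0, 4 * pi, length.out = 30),
                                 t_max = 4 * pi, grid_n = 200, seed = NULL) {
  assert_that(length(amplitudes) == 2 && length(angular_freqs) == 2 &&
                length(phases) == 2, "oscillator parameters must have length 2")
  outs <- c("y1", "y2")
  if (is.numeric(obs_times)) {
    obs_times <- setNames(rep(list(obs_times), 2L), outs)
  }
  grid <- sort(unique(c(seq(0, t_max, length.out = grid_n),
                        unlist(obs_times))))
  truth <- dplyr::bind_rows(lapply(1:2, function(j) {
    tibble::tibble(
      time = grid, output = outs[j],
      value = amplitudes[j] * sin(angular_freqs[j] * grid + phases[j]),
      derivative = amplitudes[j] * angular_freqs[j] *
        cos(angular_freqs[j] * grid + phases[j]))
  }))
  noise_sd <- noise_sd %||% (0.05 * amplitudes)
  o <- sample_observations(truth, outs, obs_times, noise_sd, seed)
  new_simulation(truth, tibble::tibble(time = numeric(), flux = character(),
                                       value = numeric()),
                 o$observations, o$noise_sd, NULL, seed,
                 list(amplitudes = amplitudes, angular_freqs = angular_freqs,
                      phases = phases))
}

#' Linear two-metabolite pathway with feedback regulation
#'
#' A constant external substrate `x1` feeds `x2`, which converts to `x3`,
#' which is degraded: `dx2/dt = v1 - v2`, `dx3/dt = v2 - v3`. The inflow
#' `v1` is saturable in `x1` and inhibited by the end product `x3`
#' (`1 / (1 + (ki x3)^h)`); the conversion `v2` is saturable in `x2` and
#' activated by `x3` (`x3 / (Ka + x3)`); the efflux `v3 = k3 x3` is first
#' order. All three flux truths are exported together with the
#' two-row stoichiometry.
#'
#' @param params Named list of kinetic constants: `x1` (constant substrate,
#'   default 2), `V1`, `K1` (inflow Vmax / Km), `ki`, `h` (inhibition strength
#'   and Hill exponent), `V2`, `K2` (conversion Vmax / Km), `Ka` (activation
#'   constant), `k3` (efflux rate).
#' @param init Positive initial concentrations `c(x2 = , x3 = )`.
#' @param noise_sd Per-output noise sd; default 1% of each output's dynamic
#'   range.
#' @param obs_times Sampling times (vector or named list).
#' @param t_max,grid_n Truth grid extent and resolution.
#' @param seed Integer seed.
#' @return A `flux_simulation` with outputs `x2`, `x3` and fluxes
#'   `v1`, `v2`, `v3`.
#' @export
simulate_linear_pathway <- function(params = list(),
                                    init = c(x2 = 0.1, x3 = 0.4),
                                    noise_sd = NULL,
                                    obs_times = seq(0, 20, length.out = 15),
                                    t_max = 20, grid_n = 200, seed = NULL) {
  p <- utils::modifyList(
    list(x1 = 2, V1 = 1, K1 = 1, ki = 1, h = 2, V2 = 2, K2 = 1, Ka = 1,
         k3 = 0.5),
    params)
  flux_fn <- function(t, y, p) {
    c(v1 = p$V1 * p$x1 / (p$K1 + p$x1) / (1 + (p$ki * y[["x3"]])^p$h),
      v2 = p$V2 * y[["x2"]] / (p$K2 + y[["x2"]]) *
        y[["x3"]] / (p$Ka + y[["x3"]]),
      v3 = p$k3 * y[["x3"]])
  }
  S <- rbind(x2 = c(1, -1, 0), x3 = c(0, 1, -1))
  colnames(S) <- c("v1", "v2", "v3")
  sim <- integrate_pathway(flux_fn, S, init, p, t_max, obs_times, grid_n)
  o <- sample_observations(sim$truth, c("x2", "x3"), obs_times, noise_sd, seed)
  new_simulation(sim$truth, sim$fluxes, o$observations, o$noise_sd,
                 stoichiometry(S), seed, p)
}

#' Branched pathway with two regulatory signals
#'
#' A Voit-type power-law (S-system) branched pathway: an input flux `v1`
#' feeds `x1`, which is drained by two branches, the conversion to `x2`
#' (`v2`, inhibited by the end product `x3`) and a side reaction (`v4`,
#' activated by `x2`); `x2` converts to the terminal product `x3` via `v3`.
#' \deqn{dx_1/dt = v_1 - v_2 - v_4,\quad dx_2/dt = v_2 - v_3,\quad
#'       dx_3/dt = v_3}
#' Only `x2` and `x3` are observed, so the usable derivative equations
#' determine `v2 = dx2/dt + dx3/dt` and `v3 = dx3/dt` uniquely (the "chain
#' differences") while `v1` and `v4` stay underdetermined; the exported
#' stoichiometry has exactly this structure.
#'
#' @param params Named list of power-law constants: rates `a1`..`a4` and
#'   kinetic orders `g21` (v2 in x1), `g23` (v2 in x3, negative =
#'   inhibition), `g32` (v3 in x2), `g41` (v4 in x1), `g42` (v4 in x2,
#'   positive = activation).
#' @param init Positive initial concentrations `c(x1 = , x2 = , x3 = )`.
#' @param noise_sd Per-output noise sd; default 1% of each observed output's
#'   dynamic range (a low noise level, so derivative predictions can be
#'   compared directly with the true fluxes).
#' @param obs_times Sampling times (vector or named list).
#' @param t_max,grid_n Truth grid extent and resolution.
#' @param seed Integer seed.
#' @return A `flux_simulation` with observed outputs `x2`, `x3`, flux truths
#'   `v1`..`v4`, and a two-row stoichiometry over the measured metabolites.
#' @export
simulate_branched_pathway <- function(params = list(),
                                      init = c(x1 = 1, x2 = 0.3, x3 = 1),
                                      noise_sd = NULL,
                                      obs_times = seq(0, 10, length.out = 15),
                                      t_max = 10, grid_n = 200, seed = NULL) {
  p <- utils::modifyList(
    list(a1 = 1, a2 = 2, g21 = 0.5, g23 = -1, a3 = 1.5, g32 = 0.5,
         a4 = 0.8, g41 = 0.5, g42 = 1),
    params)
  assert_that(p$g23 <= 0, "`g23` is an inhibition order and must be <= 0")
  flux_fn <- function(t, y, p) {
    c(v1 = p$a1,
      v2 = p$a2 * y[["x1"]]^p$g21 * y[["x3"]]^p$g23,
      v3 = p$a3 * y[["x2"]]^p$g32,
      v4 = p$a4 * y[["x1"]]^p$g41 * y[["x2"]]^p$g42)
  }
  S_full <- rbind(x1 = c(1, -1, 0, -1), x2 = c(0, 1, -1, 0),
                  x3 = c(0, 0, 1, 0))
  colnames(S_full) <- c("v1", "v2", "v3", "v4")
  sim <- integrate_pathway(flux_fn, S_full, init, p, t_max, obs_times, grid_n)
  o <- sample_observations(sim$truth, c("x2", "x3"), obs_times, noise_sd, seed)
  st <- stoichiometry(S_full[c("x2", "x3"), , drop = FALSE])
  new_simulation(sim$truth, sim$fluxes, o$observations, o$noise_sd, st,
                 seed, p)
}

#' Three-metabolite nitrogen-assimilation surrogate
#'
#' A surrogate for ammonium assimilation after an ammonium spike:
#' alpha-ketoglutarate (`aKG`) receives a constant input flux `v1` from the
#' citrate cycle, is converted to glutamate (`GLU`) by a saturable GDH-like
#' reaction `v2`, glutamate is converted to glutamine (`GLN`) by the lumped
#' GS-like flux `v3 = mutant_scale * k3 * GLU`, and glutamine is drained by a
#' first-order efflux `v4 = k4 * GLN`:
#' \deqn{d[aKG]/dt = v_1 - v_2,\; d[GLU]/dt = v_2 - v_3,\;
#'       d[GLN]/dt = v_3 - v_4.}
#' Setting `mutant_scale < 1` emulates a glutamine-synthetase-deficient
#' mutant (reduced GS expression lowers the GLU to GLN flux). The exported
#' stoichiometry declares `v4` known (tabulated from the efflux truth), so
#' `v1`, `v2`, `v3` are all estimable from the three derivative equations.
#'
#' @param params Named list: `v_in` (input flux), `k2`, `K2` (GDH-like rate /
#'   half-saturation), `k3` (GS-like rate), `k4` (glutamine efflux rate).
#' @param init Positive initial concentrations `c(aKG = , GLU = , GLN = )`;
#'   the default starts from nitrogen starvation (high aKG, low GLU/GLN).
#' @param mutant_scale Multiplier on the GS-like rate constant; 1 is wild
#'   type.
#' @param noise_sd Per-output noise sd; default 1% of dynamic range.
#' @param obs_times Sampling times (vector or named list).
#' @param t_max,grid_n Truth grid extent and resolution.
#' @param seed Integer seed.
#' @return A `flux_simulation` with outputs `aKG`, `GLU`, `GLN`, flux truths
#'   `v1`..`v4`, and a three-row stoichiometry with `v4` known.
#' @export
simulate_nitrogen_pathway <- function(params = list(),
                                      init = c(aKG = 2, GLU = 0.3, GLN = 0.1),
                                      mutant_scale = 1,
                                      noise_sd = NULL,
                                      obs_times = seq(0, 10, length.out = 12),
                                      t_max = 10, grid_n = 200, seed = NULL) {
  p <- utils::modifyList(
    list(v_in = 0.5, k2 = 1.5, K2 = 1, k3 = 0.8, k4 = 0.6), params)
  assert_that(is.numeric(mutant_scale) && mutant_scale > 0,
              "`mutant_scale` must be positive")
  p$scale <- mutant_scale
  flux_fn <- function(t, y, p) {
    c(v1 = p$v_in,
      v2 = p$k2 * y[["aKG"]] / (p$K2 + y[["aKG"]]),
      v3 = p$scale * p$k3 * y[["GLU"]],
      v4 = p$k4 * y[["GLN"]])
  }
  S_full <- rbind(aKG = c(1, -1, 0, 0), GLU = c(0, 1, -1, 0),
                  GLN = c(0, 0, 1, -1))
  colnames(S_full) <- c("v1", "v2", "v3", "v4")
  sim <- integrate_pathway(flux_fn, S_full, init, p, t_max, obs_times, grid_n)
  o <- sample_observations(sim$truth, rownames(S_full), obs_times, noise_sd,
                           seed)
  v4_truth <- sim$fluxes[sim$fluxes$flux == "v4", c("time", "value")]
  st <- stoichiometry(S_full,
                      known = list(v4 = stats::approxfun(v4_truth$time,
                                                         v4_truth$value,
                                                         rule = 2)))
  new_simulation(sim$truth, sim$fluxes, o$observations, o$noise_sd, st,
                 seed, p)
}
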