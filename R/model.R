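#' Specify a dependent multi-output GP as a convolution network
#'
#' A model is a bipartite network: latent white-noise sources on one side,
#' output processes on the other, with one Gaussian kernel per (source,
#' output) edge and one additive observation-noise term per output. Outputs
#' that share a latent source are dependent; a source with a single edge is
#' private smooth structure for one output.
#'
#' @param outputs Character vector of output labels (order fixes block order
#'   in all covariance matrices).
#' @param edges Data frame with columns `source` and `output`: one row per
#'   kernel. Every output must have at least one incident edge.
#' @return An object of class `mgp_spec`.
#' @seealso [two_output_spec()], [nitrogen_pathway_spec()]
#' @examples
#' mgp_spec(c("a", "b"),
#'          data.frame(source = c("shared", "shared", "pa"),
#'                     output = c("a", "b", "a")))
#' @export
mgp_spec <- function(outputs, edges) {
  outputs <- as.character(outputs)
  assert_that(length(outputs) >= 1L && !anyDuplicated(outputs),
              "`outputs` must be a non-empty vector of unique labels")
  assert_that(is.data.frame(edges) && all(c("source", "output") %in% names(edges)),
              "`edges` must be a data frame with columns `source`, `output`")
  edges <- tibble::tibble(source = as.character(edges$source),
                          output = as.character(edges$output))
  assert_that(all(edges$output %in% outputs),
              "every edge must point at a declared output")
  key <- paste(edges$source, edges$output, sep = "\r")
  assert_that(!anyDuplicated(key),
              "duplicate (source, output) edges: one kernel per edge")
  missing <- setdiff(outputs, edges$output)
  assert_that(length(missing) == 0L,
              paste0("outputs without any kernel edge: ",
                     paste(missing, collapse = ", ")))
  structure(
    list(outputs = outputs,
         sources = unique(edges$source),
         edges = edges,
         K = length(outputs)),
    class = "mgp_spec"
  )
}

#' @export
print.mgp_spec <- function(x, ...) {
  cat("<mgp_spec> ", x$K, " outputs, ", length(x$sources), " latent sources, ",
      nrow(x$edges), " kernels\n", sep = "")
  shared <- x$edges$source[duplicated(x$edges$source)]
  for (o in x$outputs) {
    src <- x$edges$source[x$edges$output == o]
    cat("  ", o, " <- {", paste(src, collapse = ", "), "} + noise\n", sep = "")
  }
  cat("  free hyperparameters when nothing is fixed: ",
      2L * nrow(x$edges) + x$K, "\n", sep = "")
  invisible(x)
}

#' Two correlated signals sharing one latent source
#'
#' The canonical two-output model: each signal is a superposition of a
#' convolution GP driven by a source shared between the two signals, a
#' convolution GP driven by a private source, and additive observation noise.
#' Four kernels plus two noise terms give 10 hyperparameters when nothing is
#' fixed.
#'
#' @param outputs Labels for the two signals.
#' @return An `mgp_spec` with 3 sources and 4 edges.
#' @export
two_output_spec <- function(outputs = c("y1", "y2")) {
  assert_that(length(outputs) == 2L, "`outputs` must have length 2")
  o <- as.character(outputs)
  mgp_spec(o, data.frame(
    source = c("shared", "shared", paste0("private_", o)),
    output = c(o, o)
  ))
}

#' Three-metabolite nitrogen-assimilation model structure
#'
#' Model composition for alpha-ketoglutarate (aKG), glutamate (GLU) and
#' glutamine (GLN): aKG is a sum of a private GP, a GP driven by a source
#' shared with GLU, and noise; GLN is modelled the same way with a source
#' shared with GLU; GLU is a sum of four GPs (private, shared-with-aKG,
#' shared-with-GLN, noise). aKG and GLN are conditionally linked only through
#' GLU. Seven kernels plus three noise terms give 17 hyperparameters.
#'
#' @param outputs Labels for the three metabolites, in the order
#'   (aKG, GLU, GLN).
#' @return An `mgp_spec` with 5 sources and 7 edges.
#' @export
nitrogen_pathway_spec <- function(outputs = c("aKG", "GLU", "GLN")) {
  assert_that(length(outputs) == 3L, "`outputs` must have length 3")
  o <- as.character(outputs)
  mgp_spec(o, data.frame(
    source = c(paste0("private_", o[1]), "aKG_GLU",
               paste0("private_", o[2]), "aKG_GLU", "GLU_GLN",
               paste0("private_", o[3]), "GLU_GLN"),
    output = c(o[1], o[1], o[2], o[2], o[2], o[3], o[3])
  ))
}

# --- hyperparameters ---------------------------------------------------------

edge_ids <- function(spec) paste0(spec$edges$source, "->", spec$edges$output)

#' Hyperparameter names of a model
#'
#' Log-amplitude and log-inverse-width per kernel edge, log-noise-sd per
#' output, in the canonical order used by all parameter vectors.
#' @param spec An [mgp_spec()].
#' @return Character vector of parameter names.
#' @export
param_names <- function(spec) {
  e <- edge_ids(spec)
  c(paste0("log_A[", e, "]"),
    paste0("log_b[", e, "]"),
    paste0("log_sigma[", spec$outputs, "]"))
}

#' Construct a hyperparameter vector
#'
#' Hyperparameters are stored on the log scale so that positivity of
#' amplitudes, inverse widths and noise standard deviations is automatic.
#'
#' @param spec An [mgp_spec()].
#' @param log_amplitude,log_inv_width Scalar or vector (one per edge, in
#'   `spec$edges` order) of log kernel amplitudes / log inverse widths.
#' @param log_noise_sd Scalar or vector (one per output) of log observation
#'   noise standard deviations.
#' @param fixed Character vector of parameter names (see [param_names()])
#'   held constant during fitting.
#' @return An object of class `mgp_params`: a named log-scale vector `theta`
#'   plus the fixed mask.
#' @export
mgp_params <- function(spec, log_amplitude = 0, log_inv_width = 0,
                       log_noise_sd = log(0.1), fixed = character()) {
  ne <- nrow(spec$edges); K <- spec$K
  theta <- c(rep_len(log_amplitude, ne), rep_len(log_inv_width, ne),
             rep_len(log_noise_sd, K))
  names(theta) <- param_names(spec)
  assert_that(all(is.finite(theta)), "hyperparameters must be finite")
  unknown <- setdiff(fixed, names(theta))
  assert_that(length(unknown) == 0L,
              paste0("unknown parameter names in `fixed`: ",
                     paste(unknown, collapse = ", ")))
  structure(list(theta = theta, fixed = names(theta) %in% fixed, spec_K = K),
            class = "mgp_params")
}

#' @export
print.mgp_params <- function(x, ...) {
  cat("<mgp_params> ", length(x$theta), " hyperparameters (",
      sum(!x$fixed), " free)\n", sep = "")
  print(round(x$theta, 4))
  invisible(x)
}

#' Number of free (non-fixed) hyperparameters
#' @param params An [mgp_params()] object.
#' @return Integer count.
#' @export
n_free_params <- function(params) sum(!params$fixed)

# Natural-scale kernel table for one output.
kernels_for_output <- function(spec, params, output) {
  idx <- which(spec$edges$output == output)
  ne <- nrow(spec$edges)
  tibble::tibble(
    source = spec$edges$source[idx],
    output = output,
    amplitude = exp(unname(params$theta[idx])),
    inv_width = exp(unname(params$theta[ne + idx]))
  )
}

noise_sd <- function(spec, params) {
  ne <- nrow(spec$edges)
  setNames(exp(unname(params$theta[2L * ne + seq_len(spec$K)])), spec$outputs)
}

# Replace the free entries of `params` with values from vector `free`.
set_free <- function(params, free) {
  params$theta[!params$fixed] <- free
  params
}

# --- priors ------------------------------------------------------------------

#' Independent Gaussian priors on log-scale hyperparameters
#'
#' Weakly informative priors for MAP estimation: each log-parameter gets an
#' independent normal prior. Location and scale can be scalars or named
#' vectors keyed by parameter name for per-parameter control.
#'
#' @param spec An [mgp_spec()].
#' @param location,scale Prior mean / sd on the log scale; scalar, or a named
#'   vector whose names are a subset of [param_names()] (unnamed default
#'   applies elsewhere).
#' @return A tibble with columns `parameter`, `location`, `scale` of class
#'   `mgp_priors`.
#' @export
mgp_priors <- function(spec, location = 0, scale = 1.5) {
  nm <- param_names(spec)
  expand <- function(x, default) {
    out <- rep_len(default, length(nm))
    names(out) <- nm
    if (is.null(names(x))) {
      assert_that(length(x) == 1L || length(x) == length(nm),
                  "unnamed prior settings must be scalar or full-length")
      out[] <- x
    } else {
      unknown <- setdiff(names(x), nm)
      assert_that(length(unknown) == 0L,
                  paste0("unknown parameter names in prior: ",
                         paste(unknown, collapse = ", ")))
      out[names(x)] <- x
    }
    out
  }
  loc <- expand(location, 0)
  sc <- expand(scale, 1.5)
  assert_that(all(is.finite(loc)) && all(is.finite(sc)) && all(sc > 0),
              "prior locations must be finite and scales positive")
  out <- tibble::tibble(parameter = nm, location = unname(loc), scale = unname(sc))
  class(out) <- c("mgp_priors", class(out))
  out
}

log_prior <- function(params, priors) {
  free <- !params$fixed
  if (!any(free)) return(0)
  i <- match(names(params$theta)[free], priors$parameter)
  assert_that(!anyNA(i), "priors must cover all free parameters")
  sum(dnorm(params$theta[free], priors$location[i], priors$scale[i], log = TRUE))
}

# --- time-series data --------------------------------------------------------

# Validate a long-format (output, time, value) table.
as_timeseries <- function(data, outputs = NULL, min_points = 0L,
                          replicates = FALSE) {
  assert_that(is.data.frame(data) &&
                all(c("output", "time", "value") %in% names(data)),
              "data must have columns `output`, `time`, `value`")
  data <- tibble::tibble(output = as.character(data$output),
                         time = as.numeric(data$time),
                         value = as.numeric(data$value))
  assert_that(all(is.finite(data$time)) && all(is.finite(data$value)),
              "`time` and `value` must be finite")
  if (!replicates) {
    key <- paste(data$output, data$time, sep = "\r")
    dup <- which(duplicated(key))
    assert_that(length(dup) == 0L,
                paste0("duplicate (output, time) pairs at rows: ",
                       paste(dup, collapse = ", "),
                       "; set replicates = TRUE to allow"))
  }
  if (!is.null(outputs)) {
    unknown <- setdiff(unique(data$output), outputs)
    assert_that(length(unknown) == 0L,
                paste0("data contains outputs absent from the model: ",
                       paste(unknown, collapse = ", ")))
    if (min_points > 0L) {
      n_i <- table(factor(data$output, levels = outputs))
      low <- names(n_i)[n_i < min_points]
      assert_that(length(low) == 0L,
                  paste0("each modelled output needs at least ", min_points,
                         " observations; too few for: ",
                         paste(low, collapse = ", ")))
    }
  }
  data
}

# Order observations canonically: by model output order, then time.
order_obs <- function(data, spec) {
  data[order(match(data$output, spec$outputs), data$time), , drop = FALSE]
}

#' Marginal log-likelihood of a dependent GP model
#'
#' The observation vector is jointly multivariate normal with zero mean and
#' covariance `C + diag(sigma_i^2)` built from the convolution covariance; the
#' log-likelihood is
#' \deqn{-\tfrac12 y^T K^{-1} y - \tfrac12 \log|K| - \tfrac{N}{2}\log 2\pi}
#' computed through a Cholesky factorization.
#'
#' @param data Long-format observations with columns `output`, `time`,
#'   `value`.
#' @param spec An [mgp_spec()].
#' @param params An [mgp_params()] vector.
#' @return The log-likelihood (scalar).
#' @export
log_marginal_likelihood <- function(data, spec, params) {
  data <- as_timeseries(data, spec$outputs)
  data <- order_obs(data, spec)
  obs_times <- split(data$time, factor(data$output, levels = spec$outputs))
  cb <- build_joint_covariance(spec, params, obs_times)
  y <- data$value
  n <- length(y)
  L <- chol(cb$K_obs)   # K_obs is jitter-validated by the assembly step
  alpha <- chol_solve(L, y)
  as.numeric(-0.5 * sum(y * alpha) - sum(log(diag(L))) -
               0.5 * n * log(2 * pi))
}
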