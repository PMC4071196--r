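#' Declare a stoichiometric system linking metabolite derivatives to fluxes
#'
#' The dynamics of the modelled metabolites are
#' \eqn{\mathrm{d}\mathbf{x}/\mathrm{d}t = S\,\mathbf{v}}: one row per
#' modelled metabolite, one column per flux, dimensionless coefficients.
#' Fluxes that are measured or otherwise known are supplied as time-indexed
#' values and substituted out before estimability analysis.
#'
#' @param S Numeric matrix of stoichiometric coefficients; rows are
#'   metabolites, columns are fluxes.
#' @param metabolites,fluxes Row / column labels; default to
#'   `rownames(S)` / `colnames(S)`.
#' @param known Named list mapping a flux label to its known trajectory:
#'   either a function of time or a data frame with columns `time`, `value`.
#' @return An object of class `stoichiometry`.
#' @examples
#' # linear chain x2 -> x3 with input v1 and efflux v3
#' stoichiometry(rbind(x2 = c(1, -1, 0), x3 = c(0, 1, -1)),
#'               fluxes = c("v1", "v2", "v3"))
#' @export
stoichiometry <- function(S, metabolites = rownames(S), fluxes = colnames(S),
                          known = list()) {
  S <- as.matrix(S)
  assert_that(is.numeric(S) && all(is.finite(S)),
              "`S` must be a finite numeric matrix")
  metabolites <- as.character(metabolites %||% paste0("x", seq_len(nrow(S))))
  fluxes <- as.character(fluxes %||% paste0("v", seq_len(ncol(S))))
  assert_that(length(metabolites) == nrow(S) && !anyDuplicated(metabolites),
              "`metabolites` must label the rows of S uniquely")
  assert_that(length(fluxes) == ncol(S) && !anyDuplicated(fluxes),
              "`fluxes` must label the columns of S uniquely")
  dimnames(S) <- list(metabolites, fluxes)
  assert_that(is.list(known), "`known` must be a named list")
  if (length(known)) {
    assert_that(!is.null(names(known)) && all(names(known) %in% fluxes),
                "names of `known` must be flux labels")
    ok <- vapply(known, function(k) {
      is.function(k) ||
        (is.data.frame(k) && all(c("time", "value") %in% names(k)))
    }, TRUE)
    assert_that(all(ok),
                "each known flux must be a function of time or a (time, value) data frame")
  }
  structure(list(S = S, metabolites = metabolites, fluxes = fluxes,
                 known = known),
            class = "stoichiometry")
}

#' @export
print.stoichiometry <- function(x, ...) {
  cat("<stoichiometry> ", length(x$metabolites), " metabolites, ",
      length(x$fluxes), " fluxes",
      if (length(x$known)) paste0(" (known: ",
                                  paste(names(x$known), collapse = ", "), ")"),
      "\n", sep = "")
  print(x$S)
  invisible(x)
}

# Coefficient vector a (over metabolite rows) expressing unknown flux v as
# a' (dx/dt - S_known v_known), or NULL if v is not uniquely determined.
flux_coefficients <- function(S_u, v_index, tol = 1e-8) {
  a <- as.numeric(pseudo_inverse(t(S_u)) %*%
                    replace(numeric(ncol(S_u)), v_index, 1))
  resid <- as.numeric(t(S_u) %*% a) - replace(numeric(ncol(S_u)), v_index, 1)
  if (max(abs(resid)) < tol * max(1, max(abs(S_u)))) a else NULL
}

#' Classify fluxes of a stoichiometric system by estimability
#'
#' After substituting known fluxes, a remaining flux is *estimable* when its
#' value is a unique linear combination of the metabolite derivatives and the
#' known fluxes, i.e. when its unit vector lies in the row space of the
#' reduced stoichiometric matrix. Systems with fewer independent derivative
#' equations than unknown fluxes are underdetermined: some fluxes then have
#' no unique value and are flagged rather than silently regularized.
#'
#' @param st A [stoichiometry()].
#' @param tol Relative tolerance for the row-space membership test.
#' @return A tibble with columns `flux` and `status` (`"known"`,
#'   `"estimable"` or `"underdetermined"`). The overall system class
#'   (`"uniquely determined"`, `"underdetermined"` or `"overdetermined"`) is
#'   in `attr(, "system")`, and the solved coefficient vectors in
#'   `attr(, "coefficients")`.
#' @export
classify_fluxes <- function(st, tol = 1e-8) {
  assert_that(inherits(st, "stoichiometry"), "`st` must be a stoichiometry")
  unknown <- setdiff(st$fluxes, names(st$known))
  S_u <- st$S[, unknown, drop = FALSE]
  r <- if (length(unknown)) qr(S_u)$rank else 0L
  system <- if (r < length(unknown)) {
    "underdetermined"
  } else if (r < nrow(st$S)) {
    "overdetermined"
  } else {
    "uniquely determined"
  }
  coefs <- list()
  status <- setNames(rep("known", length(st$fluxes)), st$fluxes)
  for (v in unknown) {
    a <- flux_coefficients(S_u, match(v, unknown), tol)
    if (is.null(a)) {
      status[v] <- "underdetermined"
    } else {
      status[v] <- "estimable"
      coefs[[v]] <- setNames(a, st$metabolites)
    }
  }
  out <- tibble::tibble(flux = st$fluxes, status = unname(status))
  attr(out, "system") <- system
  attr(out, "coefficients") <- coefs
  out
}

# Evaluate known fluxes on the prediction grid.
eval_known <- function(st, times, interpolate_known) {
  vapply(names(st$known), function(v) {
    k <- st$known[[v]]
    if (is.function(k)) return(as.numeric(k(times)))
    i <- match(times, k$time)
    if (anyNA(i)) {
      assert_that(isTRUE(interpolate_known),
                  paste0("known flux `", v, "` is not tabulated at the ",
                         "prediction grid; set interpolate_known = TRUE ",
                         "to interpolate linearly"))
      approx(k$time, k$value, xout = times, rule = 2)$y
    } else {
      k$value[i]
    }
  }, numeric(length(times)))
}

#' Estimate time-varying fluxes from a derivative posterior
#'
#' Solves the stoichiometric linear system for each estimable flux and pushes
#' the joint Gaussian posterior over metabolite derivatives through it: each
#' estimable flux is a linear combination \eqn{a^T(\dot x - S_k v_k)} of the
#' derivative processes and known fluxes, so its posterior is Gaussian with
#' mean \eqn{a^T(\hat{\dot x} - S_k v_k)} and variance \eqn{a^T \Sigma a}
#' taken from the joint derivative covariance (exact propagation, no
#' linearization needed).
#'
#' @param prediction An `mgp_prediction` from [posterior_joint()] /
#'   [predict.mgp_fit()] containing derivative predictions, on a common time
#'   grid, for every metabolite row of the stoichiometry.
#' @param st A [stoichiometry()].
#' @param min_norm If `TRUE`, also report minimum-norm (pseudoinverse)
#'   trajectories for underdetermined fluxes, with a warning; these are one
#'   representative of an infinite solution family, not estimates.
#' @param interpolate_known Allow linear interpolation of tabulated known
#'   fluxes onto the prediction grid.
#' @param tol Estimability tolerance, passed to [classify_fluxes()].
#' @return An object of class `flux_estimate`: a tibble with columns `flux`,
#'   `time`, `mean`, `sd`, `status`; the per-flux classification is in
#'   `attr(, "classification")`. Underdetermined fluxes carry no rows unless
#'   `min_norm = TRUE`.
#' @export
estimate_fluxes <- function(prediction, st, min_norm = FALSE,
                            interpolate_known = FALSE, tol = 1e-8) {
  assert_that(inherits(prediction, "mgp_prediction"),
              "`prediction` must be an mgp_prediction")
  assert_that(inherits(st, "stoichiometry"), "`st` must be a stoichiometry")
  idx <- attr(prediction, "index")
  Sigma <- attr(prediction, "covariance")
  assert_that(!is.null(Sigma), "prediction carries no joint covariance")

  m <- length(st$metabolites)
  d_rows <- lapply(st$metabolites, function(mb) {
    rows <- which(idx$output == mb & idx$quantity == "derivative")
    assert_that(length(rows) > 0L,
                paste0("no derivative prediction for metabolite `", mb, "`"))
    rows[order(idx$time[rows])]
  })
  times <- idx$time[d_rows[[1L]]]
  same <- vapply(d_rows, function(r) identical(idx$time[r][order(idx$time[r])],
                                               times), TRUE)
  assert_that(all(same),
              "metabolites must share a common derivative prediction grid")
  n_t <- length(times)

  # derivative means (n_t x m) and the known-flux contribution
  D <- vapply(d_rows, function(r) prediction$mean[r], numeric(n_t))
  rhs <- D
  if (length(st$known)) {
    Vk <- eval_known(st, times, interpolate_known)
    rhs <- D - Vk %*% t(st$S[, colnames(Vk), drop = FALSE])
  }

  cls <- classify_fluxes(st, tol)
  coefs <- attr(cls, "coefficients")
  unknown <- setdiff(st$fluxes, names(st$known))
  S_u <- st$S[, unknown, drop = FALSE]

  # per-time derivative covariance blocks (m x m), in metabolite order
  row_mat <- do.call(cbind, d_rows)          # n_t x m row indices
  Sig_t <- lapply(seq_len(n_t), function(k) {
    Sigma[row_mat[k, ], row_mat[k, ], drop = FALSE]
  })

  # consistency of an overdetermined substitution: left-null-space
  # combinations of the reduced system must vanish within posterior noise
  if (length(unknown) && nrow(st$S) > qr(S_u)$rank) {
    N <- svd(S_u, nu = nrow(S_u))$u[, -seq_len(qr(S_u)$rank), drop = FALSE]
    z <- vapply(seq_len(n_t), function(k) {
      mu <- as.numeric(crossprod(N, rhs[k, ]))
      s <- sqrt(pmax(diag(crossprod(N, Sig_t[[k]] %*% N)), 0))
      max(abs(mu) / (s + 1e-8 * max(1, max(abs(rhs)))))
    }, numeric(1))
    assert_that(max(z) < 10,
                "inconsistent known-flux substitution: the overdetermined system's consistency constraints are violated far beyond posterior uncertainty")
  }

  rows <- list()
  add_rows <- function(flux, mean, var, status) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      flux = flux, time = times, mean = mean,
      sd = sqrt(pmax(var, 0)), status = status)
  }
  for (v in st$fluxes) {
    s <- cls$status[cls$flux == v]
    if (s == "known") {
      kv <- eval_known(st, times, interpolate_known)[, v]
      add_rows(v, kv, 0, "known")
    } else if (s == "estimable") {
      a <- coefs[[v]]
      mu <- as.numeric(rhs %*% a)
      va <- vapply(Sig_t, function(S) as.numeric(crossprod(a, S %*% a)),
                   numeric(1))
      add_rows(v, mu, va, "estimable")
    } else if (isTRUE(min_norm)) {
      P <- pseudo_inverse(S_u)[match(v, unknown), , drop = FALSE]
      mu <- as.numeric(rhs %*% t(P))
      va <- vapply(Sig_t, function(S) as.numeric(P %*% S %*% t(P)), numeric(1))
      add_rows(v, mu, va, "minimum_norm")
    }
  }
  if (isTRUE(min_norm) && any(cls$status == "underdetermined")) {
    warn(paste0("minimum-norm trajectories reported for underdetermined ",
                "fluxes (", paste(cls$flux[cls$status == "underdetermined"],
                                  collapse = ", "),
                "); these are one representative of an infinite solution family"))
  }

  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(flux = character(), time = numeric(), mean = numeric(),
                   sd = numeric(), status = character())
  }
  structure(out, classification = cls, system = attr(cls, "system"),
            class = c("flux_estimate", class(out)))
}

#' @export
print.flux_estimate <- function(x, ...) {
  cls <- attr(x, "classification")
  cat("<flux_estimate> system ", attr(x, "system"), "\n", sep = "")
  for (i in seq_len(nrow(cls))) {
    cat("  ", cls$flux[i], ": ", cls$status[i], "\n", sep = "")
  }
  NextMethod()
}

#' Tidy a flux estimate
#' @param x A `flux_estimate`.
#' @param ... Unused.
#' @return A plain tibble (`flux`, `time`, `mean`, `sd`, `status`).
#' @method tidy flux_estimate
#' @export
tidy.flux_estimate <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("flux", "time", "mean", "sd", "status")])
}

#' Plot estimated flux trajectories
#'
#' Mean flux curves with +/- 2 posterior standard deviation ribbons, one
#' facet per flux. A ground-truth table (`flux`, `time`, `value`) can be
#' overlaid as a dashed line.
#'
#' @param object A `flux_estimate`.
#' @param truth Optional tibble of true fluxes with columns `flux`, `time`,
#'   `value`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flux_estimate
#' @export
autoplot.flux_estimate <- function(object, truth = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - 2 * .data$sd,
                   ymax = .data$mean + 2 * .data$sd),
      fill = "palevioletred", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "palevioletred4") +
    ggplot2::facet_wrap(~flux, scales = "free_y") +
    ggplot2::labs(x = "time", y = "flux")
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_line(
      data = truth, ggplot2::aes(x = .data$time, y = .data$value),
      linetype = "dashed", inherit.aes = FALSE)
  }
  p
}
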