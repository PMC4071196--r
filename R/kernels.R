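#' Gaussian smoothing kernel attached to one (source, output) edge
#'
#' In the process-convolution construction each output process is a sum of
#' convolutions of latent white-noise sources with Gaussian impulse-response
#' kernels \eqn{h(t) = A \exp(-b t^2 / 2)}. A kernel is identified by the
#' latent source it smooths and the output it feeds; sharing a source between
#' two outputs is what induces cross-correlation between them.
#'
#' @param amplitude Kernel amplitude \eqn{A > 0} (signal units).
#' @param inv_width Inverse squared width \eqn{b > 0} (1/time^2); larger
#'   values give rougher, faster-varying processes.
#' @param source Label of the latent white-noise source.
#' @param output Label of the output process the kernel feeds.
#' @return A one-row tibble with columns `source`, `output`, `amplitude`,
#'   `inv_width`. Several kernels are combined with [rbind()] /
#'   [dplyr::bind_rows()] into a kernel table.
#' @examples
#' k <- kernel_spec(1, 1)
#' cov_yy(k, k, 0)  # sqrt(pi)
#' @export
kernel_spec <- function(amplitude, inv_width, source = "s1", output = "y1") {
  assert_that(is.numeric(amplitude) && all(is.finite(amplitude)) && all(amplitude > 0),
              "`amplitude` must be a finite positive number")
  assert_that(is.numeric(inv_width) && all(is.finite(inv_width)) && all(inv_width > 0),
              "`inv_width` must be a finite positive number")
  tibble::tibble(
    source = as.character(source),
    output = as.character(output),
    amplitude = as.numeric(amplitude),
    inv_width = as.numeric(inv_width)
  )
}

check_kernel_table <- function(k, arg = "kernels") {
  assert_that(is.data.frame(k) &&
                all(c("source", "output", "amplitude", "inv_width") %in% names(k)),
              sprintf("`%s` must be a kernel table (see kernel_spec())", arg))
  assert_that(all(is.finite(k$amplitude)) && all(k$amplitude > 0) &&
                all(is.finite(k$inv_width)) && all(k$inv_width > 0),
              sprintf("`%s` has non-positive or non-finite kernel parameters", arg))
  key <- paste(k$source, k$output, sep = "\r")
  assert_that(!anyDuplicated(key),
              sprintf("`%s` has duplicate (source, output) kernels; one kernel per edge", arg))
  invisible(k)
}

# Matched kernel pairs between two outputs: all (h in ki, g in kj) with a
# shared latent source. Returns a list of parallel parameter vectors.
shared_pairs <- function(ki, kj) {
  idx <- merge(
    data.frame(source = ki$source, h = seq_len(nrow(ki))),
    data.frame(source = kj$source, g = seq_len(nrow(kj)))
  )
  if (nrow(idx) == 0L) return(NULL)
  list(
    Ah = ki$amplitude[idx$h], bh = ki$inv_width[idx$h],
    Ag = kj$amplitude[idx$g], bg = kj$inv_width[idx$g]
  )
}

# One convolution pair's contribution to cov(Y_i(t), Y_j(t')) and its first
# and second derivative forms, evaluated at separations d = t - t'.
# Closed form of \int h(t - s) g(t' - s) ds for unit-spectral-density white
# noise: A_h A_g sqrt(2 pi / (b_h + b_g)) exp(-sig d^2 / 2),
# sig = b_h b_g / (b_h + b_g).
pair_cov <- function(p, d, type) {
  sig <- p$bh * p$bg / (p$bh + p$bg)
  pref <- p$Ah * p$Ag * sqrt(2 * pi / (p$bh + p$bg))
  out <- 0
  for (m in seq_along(sig)) {
    base <- pref[m] * exp(-0.5 * sig[m] * d^2)
    out <- out + switch(type,
      yy = base,
      uy = -sig[m] * d * base,
      uu = sig[m] * (1 - sig[m] * d^2) * base
    )
  }
  out
}

cov_core <- function(kernels_i, kernels_j, d, type) {
  check_kernel_table(kernels_i, "kernels_i")
  check_kernel_table(kernels_j, "kernels_j")
  assert_that(is.numeric(d) && all(is.finite(d)), "`d` must be finite numeric")
  p <- shared_pairs(kernels_i, kernels_j)
  if (is.null(p)) return(d * 0)
  pair_cov(p, d, type)
}

#' Covariance calculus for convolution-constructed processes
#'
#' Closed-form auto/cross covariances between two outputs of the shared-source
#' convolution model and their derivative processes, as functions of the
#' signed temporal separation `d = t - t'`.
#'
#' * `cov_yy(i, j, d)`: covariance of the original processes,
#'   \eqn{\mathrm{cov}(Y_i(t), Y_j(t'))}. Sum over kernel pairs sharing a
#'   source of \eqn{A_h A_g \sqrt{2\pi/(b_h+b_g)} e^{-\sigma d^2/2}} with
#'   \eqn{\sigma = b_h b_g/(b_h+b_g)}. Even in `d`; zero when the outputs
#'   share no source.
#' * `cov_uy(i, j, d)`: covariance between the derivative process of output
#'   *i* at `t` and output *j* at `t'`, i.e. \eqn{\partial/\partial t} of
#'   `cov_yy` at `d = t - t'`. Odd in `d`; the covariance with the derivative
#'   taken on the second argument is the negative, `-cov_uy(i, j, d)`.
#' * `cov_uu(i, j, d)`: covariance between the two derivative processes,
#'   \eqn{-\,\mathrm{d}^2/\mathrm{d}d^2} of `cov_yy`.
#'
#' @param kernels_i,kernels_j Kernel tables (see [kernel_spec()]) for outputs
#'   *i* and *j*; sources are matched by label.
#' @param d Signed temporal separation(s) `t - t'`; vectorized.
#' @return Numeric of the same shape as `d`.
#' @examples
#' k <- kernel_spec(1, 1)
#' cov_uu(k, k, 0)  # sqrt(pi) / 2
#' @export
cov_yy <- function(kernels_i, kernels_j, d) cov_core(kernels_i, kernels_j, d, "yy")

#' @rdname cov_yy
#' @export
cov_uy <- function(kernels_i, kernels_j, d) cov_core(kernels_i, kernels_j, d, "uy")

#' @rdname cov_yy
#' @export
cov_uu <- function(kernels_i, kernels_j, d) cov_core(kernels_i, kernels_j, d, "uu")

# Dense covariance block between two sets of time points.
# type: "yy" cov(Y_i(ti), Y_j(tj)); "uy" cov(U_i(ti), Y_j(tj));
#       "yu" cov(Y_i(ti), U_j(tj)); "uu" cov(U_i(ti), U_j(tj)).
block_cov <- function(kernels_i, kernels_j, ti, tj, type) {
  ni <- length(ti); nj <- length(tj)
  if (ni == 0L || nj == 0L) return(matrix(0, ni, nj))
  p <- shared_pairs(kernels_i, kernels_j)
  if (is.null(p)) return(matrix(0, ni, nj))
  D <- outer(ti, tj, "-")
  if (type == "yu") {
    # derivative on the second argument flips the sign of the odd form
    -pair_cov(p, D, "uy")
  } else {
    pair_cov(p, D, type)
  }
}
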