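---
title: "Dependent Gaussian processes, derivative processes, and dynamic flux estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dependent Gaussian processes, derivative processes, and dynamic flux estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxgp)
```

## The model

`fluxgp` models a set of $K$ metabolite concentration time courses as a
dependent multi-output Gaussian process built by *process convolution*: each
output $Y_i(t)$ is a sum of convolutions of latent white-noise sources
$X_m(t)$ with Gaussian impulse-response kernels
$h(t) = A\,e^{-b t^2/2}$, plus i.i.d. observation noise,

$$Y_i(t) = \sum_{m \in \mathrm{sources}(i)} (h_{mi} * X_m)(t) + W_i(t),
  \qquad W_i(t) \sim \mathcal N(0, \sigma_i^2).$$

Outputs that share a source are correlated; a source with a single edge is
private smooth structure. The white-noise sources have unit spectral density
— all scale lives in the kernel amplitudes, which removes a non-identifiable
amplitude-times-density product. Kernels are zero-centred (no temporal lag):
the systems modelled here have no transport delays, and a lag parameter
would be the natural extension point if they did.

For Gaussian kernels the convolution integral is closed-form. A kernel pair
$(A_h, b_h)$, $(A_g, b_g)$ sharing a source contributes

$$\mathrm{cov}(Y_i(t), Y_j(t')) =
  A_h A_g \sqrt{\tfrac{2\pi}{b_h + b_g}}\;
  e^{-\frac{1}{2}\sigma d^2}, \qquad
  \sigma = \tfrac{b_h b_g}{b_h + b_g},\; d = t - t',$$

and `cov_yy()` sums these over shared pairs. With one output and one kernel
this is exactly a squared-exponential covariance with variance
$A^2\sqrt{\pi/b}$ and inverse squared length-scale $b/2$ — the single-output
sanity check the tests enforce entrywise to $10^{-12}$.

### Derivative processes

Differentiation is linear, so $U_i = \mathrm{d}Y_i/\mathrm{d}t$ (noise term
excluded) is again a Gaussian process driven by the *same* sources, and the
joint law of all outputs and derivatives is Gaussian with closed-form blocks:

* $\mathrm{cov}(U_i(t), Y_j(t')) = \partial_t\,\mathrm{cov}(Y_i, Y_j)
  = -\sigma d \cdot [\text{pair term}]$ (`cov_uy`), odd in $d$;
* $\mathrm{cov}(U_i(t), U_j(t')) = -\,\mathrm{d}^2/\mathrm{d}d^2$ of the pair
  term $= \sigma(1 - \sigma d^2)\cdot[\text{pair term}]$ (`cov_uu`), even in
  $d$ and positive at $d = 0$.

The sign convention is fixed as $d = t - t'$ with the derivative taken on
the **first** argument; the transposed block flips the sign. Both identities
are pinned down by finite-difference oracles in the test suite (200 random
configurations, absolute error below $10^{-5}$), so the convention cannot
silently drift.

`build_joint_covariance()` assembles the blocks over observed points, test
function points and test derivative points; `posterior_joint()` conditions
the joint zero-mean Gaussian on the data, giving coherent function and
derivative predictions with a full joint covariance. The reported bands are
**latent-function** bands (no observation-noise term), matching how smooth
model curves are usually drawn through noisy data points;
`include_noise = TRUE` switches to data-space bands.

## From derivatives to fluxes

The stoichiometric relation $\mathrm{d}\mathbf x/\mathrm{d}t = S\,\mathbf v$
links derivatives to fluxes. After substituting fluxes declared known, a
flux is *estimable* when its unit vector lies in the row space of the
reduced matrix $S_u$ — equivalently when some $\mathbf a$ solves
$S_u^\top \mathbf a = e_v$ (checked by least squares with relative tolerance
$10^{-8}$). Its posterior is then exactly Gaussian,

$$v(t) \sim \mathcal N\!\big(\mathbf a^\top(\hat{\dot{\mathbf x}}(t) - S_k \mathbf v_k(t)),\;
  \mathbf a^\top \dot\Sigma(t)\, \mathbf a\big),$$

with $\dot\Sigma(t)$ the cross-output derivative covariance at time $t$
taken from the joint posterior. Fluxes that are not uniquely determined are
reported as `underdetermined`, with no numbers: resolving them would require
extra information, and a silent minimum-norm solution would be a modelling
claim the data cannot support. A pseudoinverse trajectory is available
behind `min_norm = TRUE`, with a warning, for exploration only. When the
reduced system is overdetermined (dependent rows), its left-null-space
consistency constraints are checked against the posterior uncertainty and a
gross violation (|z| ≥ 10) raises an error, since it means the declared
known fluxes contradict the data.

## Hyperparameter estimation

All hyperparameters — one $(A, b)$ pair per kernel edge and one $\sigma_i$
per output — are stored and optimized on the log scale, which enforces
positivity without constrained optimization. They get independent Gaussian
priors on the log scale (default location 0, scale 1.5): weakly informative,
keeps the MAP objective smooth, and makes prior draws usable as optimizer
starts. `mgp_fit()` maximizes log marginal likelihood plus log prior with a
multistart Nelder–Mead simplex (default 10 starts drawn from the priors,
convergence tolerance $10^{-8}$ on the objective, at most 2000 iterations
per start); a derivative-free method is deliberate, as the objective is
cheap (one Cholesky of the $N \times N$ observation covariance per
evaluation) and simplex search is robust to the multimodality that
width/amplitude trade-offs create. Starts with non-finite objectives are
discarded; if no start improves on its initial point the best point seen is
returned with a warning rather than an error.

Any subset of parameters can be held fixed via `fixed` (e.g. fixing
amplitudes and noise levels and inferring only the widths — both
all-free and partially-fixed configurations are supported because either may
be appropriate depending on how much is known about the measurement error).
`center = TRUE` subtracts per-output sample means before fitting — the GP
prior has mean zero, so outputs with large offsets (concentrations far from
zero) should be centred — and restores the means at prediction.

### Numerical choices

* **Jitter**: the observed covariance block gets a diagonal jitter starting
  at $10^{-10}\cdot\overline{\mathrm{diag}}$, escalating tenfold to at most
  $10^{-6}\cdot\overline{\mathrm{diag}}$, after which a conditioning error
  naming the offending block is raised. The jitter is part of the model's
  covariance definition: the test oracles evaluate the same jittered matrix.
* **Negative variances** from round-off are clipped at zero within a
  $10^{-10}$ (relative to the prior variance scale) tolerance; anything
  beyond raises a hard error, since it indicates a real bug rather than
  round-off.
* **Ordering**: observations are canonically ordered by model output order
  and time, making the likelihood invariant to input row order.
* **Degenerate inputs**: non-positive kernel parameters, non-finite
  hyperparameters, duplicate (source, output) edges, outputs with no kernel,
  duplicate (output, time) observations (without the replicate flag) and
  sub-3-point outputs are all rejected with named errors.

## The synthetic generators

The four generators produce the study systems with exact ground truth:
trajectories, derivatives (the ODE right-hand side on the truth grid, so
$\dot{\mathbf x} = S\mathbf v$ holds to integrator accuracy) and fluxes,
plus noisy observations reproducible from a seed.

* `simulate_oscillators()`: two sinusoids $A_i\sin(\omega_i t + \phi_i)$
  with analytic derivative truth. Defaults: unit amplitudes and frequencies,
  phases $(0, \pi/3)$, 30 regular samples over two periods, noise sd 5% of
  amplitude.
* `simulate_linear_pathway()`: a two-state system fed by a constant external
  substrate ($x_1 = 2$), with saturable (Michaelis–Menten-type) kinetics:
  the inflow is inhibited by the end product ($1/(1 + (k_i x_3)^h)$), the
  conversion is activated by it ($x_3/(K_a + x_3)$), and the efflux is first
  order. The defaults relax to a stable steady state where all three fluxes
  agree, which the tests verify to 1% over a long horizon.
* `simulate_branched_pathway()`: a power-law (S-system style) branched
  pathway — input $v_1$ into $x_1$; conversion $v_2$ to $x_2$ inhibited by
  $x_3$ (negative kinetic order); conversion $v_3$ to the terminal product
  $x_3$; side branch $v_4$ out of $x_1$ activated by $x_2$. Only $x_2, x_3$
  are observed, so exactly $v_2 = \dot x_2 + \dot x_3$ and $v_3 = \dot x_3$
  are estimable and $v_1, v_4$ are underdetermined. Noise defaults to 1% of
  each observed output's dynamic range — low, so that derivative predictions
  can be compared directly against the true fluxes.
* `simulate_nitrogen_pathway()`: a three-metabolite ammonium-assimilation
  surrogate (αKG → GLU → GLN with an input flux and a first-order GLN
  efflux), starting from nitrogen starvation (high αKG, low GLU/GLN). The
  GLU→GLN conversion lumps the synthetase/synthase steps into one flux,
  because concentration data alone cannot discriminate between them;
  `mutant_scale < 1` scales its rate constant down to emulate a
  glutamine-synthetase-deficient strain. The exported stoichiometry declares
  the efflux known (tabulated from truth), leaving $v_1, v_2, v_3$ all
  estimable.

The ODE generators integrate with `deSolve::ode` (lsoda, stiff-capable,
rtol $10^{-8}$, atol $10^{-10}$) on a 200-point truth grid, so truth error
is negligible against GP tolerances. Parameter values are chosen once to
give a visible transient and relaxation inside the observation window;
the accompanying checks are *recovery* checks on self-generated truth, not
trajectory matching against any external dataset.

What the generators deliberately do **not** emulate: replicate measurements
with shared systematic error, non-Gaussian or heteroscedastic noise,
measurement-limit censoring, and model mismatch in $S$. Passing tests
therefore demonstrate correctness of the calculus and calibration of the
pipeline under its own assumptions, not robustness to assumption violations
in real data.

## Problem sizes and what the checks compute

The test suite and `scripts/acceptance.R` use deliberately small problems —
two or three outputs, 24–36 observations, 41–101-point prediction grids,
20 fit replicates, 10–20 thousand Monte-Carlo draws — sizes at which every
quantity can be cross-checked against an independent oracle (quadrature of
the defining integral, finite differences, brute-force dense conditioning,
empirical moments of draws) in seconds. The oscillator acceptance check
fits both signals jointly and compares the derivative posterior with the
analytic $A\omega\cos$ truth over the interior 80% of the window: root mean
squared error below $0.1\,A\omega$ per signal, and the ±2 sd band covering
truth at ≥ 90% of interior points pooled over the two signals. Pointwise
coverage of a plug-in MAP band fluctuates from one noise realization to the
next (replicates around the high-80s to 100% range), which is why the band
check pools both signals and the noise-recovery check uses the median over
20 replicates.

## Known limitations

* MAP plug-in prediction ignores hyperparameter uncertainty, so bands can be
  slightly overconfident at small sample sizes; full posterior sampling of
  hyperparameters is the natural extension.
* Dense Cholesky costs $O(N^3)$: fine for typical metabolomic time courses
  (tens of points per metabolite), not for hundreds of outputs.
* One-dimensional inputs (time) only, Gaussian kernels only, first
  derivatives only.
* Estimability analysis is exact linear algebra on $S$; it does not attempt
  to resolve underdetermined fluxes via positivity or smoothness side
  information.
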