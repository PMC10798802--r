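---
title: "Estimating conditional hazard and distribution functions with neural networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating conditional hazard and distribution functions with neural networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condhaz)
```

## The model

condhaz estimates the conditional hazard function of a failure time — and,
through it, the conditional survival or distribution function — without any
model structure beyond smoothness. Write $h(t, x(t)) = \log \lambda(t \mid
x(t))$ for the log conditional hazard given the covariates in force at $t$.
Working on the log scale removes the positivity constraint on $\lambda$, and
whatever function $h$ we plug into

$$S(t \mid \tilde x(t)) = \exp\Big\{-\int_0^t e^{h(s, x(s))}\,ds\Big\}$$

is automatically a valid survival function: non-increasing and in $(0, 1]$.
That validity-by-construction is the central design point of the package —
nothing downstream ever needs to re-monotonise a curve.

With right-censored observations $(y_i, \delta_i, \tilde x_i(\cdot))$,
$i = 1,\dots,n$, censoring independent of failure given covariates, and
external (non-internal) covariate paths, the full log likelihood is

$$\ell_n = \sum_{i=1}^n \Big\{ h(y_i, x_i(y_i))\,\delta_i -
  \int_0^{y_i} e^{h(t, x_i(t))}\,dt \Big\}.$$

The integral is discretised on the grid of the observed times themselves,
$t_1 < \dots < t_m$ (tied times collapse to one grid point — duplicates would
create zero-width intervals that contribute nothing). This is precisely the
counting-process data expansion used for Cox regression with time-varying
covariates: subject $i$ contributes one row per grid point $t_j \le y_i$, and
minimising

$$\mathrm{loss}(h) = \frac1n \sum_i \sum_j \mathbf 1(t_j \le y_i)
  \big[ e^{h(t_j, x_i(t_j))} (t_j - t_{j-1}) - h(t_j, x_i(t_j))\,\delta_{ij}
  \big], \qquad t_0 = 0,$$

with $\delta_{ij} = \delta_i \mathbf 1(t_j = y_i)$, is numerical integration
of $-\ell_n / n$ on the expanded rows. Because no risk set needs to be
formed, the loss decomposes over rows and trains with ordinary minibatch
stochastic gradients.

### Uncensored responses

For a continuous response on the whole real line the same machinery applies
with $\delta_i \equiv 1$ and integration from $-\infty$. The interval
$(-\infty, t_1]$ cannot carry a Riemann sum, so the distribution function is
pinned to the empirical mass $F(t_1 \mid x) = 1/n$ there; the corresponding
first row of each subject is kept in the expanded table for bookkeeping but
excluded from the loss (its contribution is constant in $h$). The estimate is

$$\widehat F(y \mid x) = \mathbf 1(t_1 \le y)\Big\{1 - \tfrac{n-1}{n}
 \exp\Big(-\sum_{j \ge 2,\; t_j \le y} e^{\hat h(t_j, x)}(t_j - t_{j-1})\Big)
 \Big\},$$

non-decreasing and bounded in $[0, 1)$ for any finite $\hat h$. Between grid
points we evaluate at the largest grid point $\le y$ (the step-function
convention), and beyond $t_m$ the curve is held constant: the discretised
cumulative hazard has support only on observed times, so extrapolating the
hazard would be invention. From $\widehat F$ the package derives conditional
means (the Riemann–Stieltjes sum $\sum_j t_j\,\Delta\widehat F(t_j)$),
quantiles by the left-continuous generalised inverse
$Q(p) = \min\{t_j : \widehat F(t_j) \ge p\}$, and equal-tailed predictive
intervals $[Q((1-\alpha)/2),\, Q((1+\alpha)/2)]$. When $\widehat F$ never
reaches $p$ (its supremum is below 1 by construction) the last grid point is
returned; this matters only for extreme upper quantiles.

## The network and the training protocol

$h$ is a fully connected feed-forward network: inputs $(t_{j-1}, t_j,
x(t_j))$, two hidden layers of 64 rectified-linear units, biases in every
layer, and a single linear output. Training uses Adam (initial learning rate
0.001, $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-7}$) over
minibatches of 100 expanded rows, with Glorot-uniform initial weights and
zero biases. Inputs are standardised by training-set mean and SD (times at
the scale of the simulation horizon, $\tau = 100$, otherwise stall
training); the transform is stored with the model.

Early stopping guards against over-fitting: the sample is split 1:1 into a
training and a validation half, and training stops once the validation loss
has failed to improve for 10 consecutive epochs, restoring the
best-validation weights. We interpret the stopping "steps" as epochs with
best-weight restoration, which is the standard practice. To use all data,
the fit is repeated with the two halves swapped and the two networks'
outputs are averaged pointwise *on the $h$ scale* — the averaged object is
the networks' output, the log hazard; averaging on the probability scale
would be the other defensible reading, but the reconstruction from the
averaged $h$ keeps all validity guarantees trivially.

Two choices here were genuinely open:

* **Validation grid.** The validation loss is the same discretised
  likelihood evaluated on the validation subjects expanded on *their own*
  observed-time grid. Evaluating them on the training grid would be equally
  defensible; using the fold's own grid makes the validation loss a
  self-contained estimate of the population loss.
* **Prediction grid after swapping.** Each half-fit carries its own grid.
  The final estimator reconstructs curves on the pooled grid of all observed
  times, with the full-sample $n$ in the $1/n$ mass — the finer partition
  uses all the data and only refines the Riemann sum.

A hyperparameter grid search (nodes $\{64, 128, 256\}$ × learning rate
$\{0.1, 0.01, 0.001, 0.0001\}$ × batch $\{64, 128, 256\}$, 36 candidates,
minimal validation loss, ties to the earliest entry) is available via
`tune_hyperparameters()`; the simulations all use the fixed defaults above.

### Numerical guards

* $h$ is clamped to $[-30, 30]$ inside $e^h$ during loss evaluation and
  curve reconstruction (configurable); unconstrained outputs can transiently
  explode early in training. The linear $h\,\delta_{ij}$ term is not
  clamped, so the gradient still points the right way.
* Reconstructed survival values are floored at $10^{-15}$ — small enough to
  be irrelevant statistically, large enough to survive the `1 - x` round
  trip in double precision, keeping $\widehat S \in (0,1]$ and
  $\widehat F \in [0,1)$ bitwise true even for extreme $h$.
* Probabilities inside the binomial log-likelihood are clipped below at
  $10^{-12}$, with a warning when clipping activates.

## What the generators emulate

`sim_censored()` reproduces the package's censored validation design: a
scaled Beta(8, 1) baseline hazard $\lambda_0(t) = 8 (t/\tau)^7 / (1 -
(t/\tau)^8)$ on $\tau = 100$ (taken literally as printed, without a $1/\tau$
Jacobian factor — only the shape matters for the comparison), a two-harmonic
Fourier covariate $x_1(t)$ with U(0,1) coefficients, a step covariate
$x_2(t) = \mathbf 1(t > q)$ with $q \sim U(0, \tau)$, and static $x_3 \sim$
Bernoulli(0.6), $x_4 \sim$ Poisson(2) truncated at 5, $x_5 \sim$ Beta(2, 5).
Truncation is true rejection resampling, not capping, which would create
point masses. The proportional-hazards setup uses log relative hazard
$2x_1(t) + 2x_2(t) + 2x_3 + 2x_4 + 2x_5$; the non-proportional setup
squares $x_1$ and replaces the additive $x_3, x_4$ terms with an
interaction. Failure times invert the survival function computed as a
Riemann sum on a $\Delta s = 0.01$ grid ($T = \sup\{t : S(t) \ge u\}$,
$u \sim U(0,1)$); the rare draw that survives the horizon is set to $\tau$
and treated as censored there. Exponential censoring rates are calibrated by
bisection on a 20,000-subject pilot to hit the target fraction (20% / 50%)
within 0.01.

`sim_uncensored()` draws $y = x_1^2 + x_2 x_3 + x_3 x_4 + x_5 +
\varepsilon\,g(x)$ with the stated covariate laws and a mixture error built
from a latent $x_6$: $N(-2,1)$, $N(0,1)$ and $0.5 x_6^2$ with weights
(0.1, 0.7, 0.2). Setup 1 takes $x_6 \sim N(1,1)$ independent and $g = c$;
Setup 2 takes $x_6 \mid x_1 \sim N(1 + 0.5 x_1,\, 0.75)$ (conditional
variance 0.75) and $g = c\,x_1^2$, making the error heteroscedastic and
correlated with the covariates — under this construction
$E[\varepsilon \mid x_1] \ne 0$, which is exactly what defeats the L2 mean
fit plus residual shift. The latent $x_6$ is never exposed as a predictor:
it exists only to build the error, and exposing it would make Setup 2
trivial. The true conditional CDF has a closed form — the $0.5 x_6^2$
component is a plain normal interval probability — so the oracle used in
calibration and MADE checks is exact rather than Monte-Carlo; when
$g(x) = 0$ (Setup 2 at $x_1 = 0$) it degenerates to a step at the mean.

`sim_kernel_example()` provides the low-dimensional designs where kernel
smoothing is at its best: $y = 2\sin(3.1416\,x) + \varepsilon$ with $x$ and
$\varepsilon$ triangular on $[-1, 1]$, and a 2-D variant adding a uniform
$x_2$ to the mean. Estimates are scored by MADE on a regular grid (steps
0.067 in each covariate axis, 0.054 in the response axis) spanning the
covariate support and the theoretical response support ($[-3,3]$ in 1-D,
$[-4,4]$ in 2-D), restricted to points with true $F \in [0.001, 0.999]$.

What the generators do *not* emulate: covariate measurement error, internal
(endogenous) covariate processes, informative censoring, left truncation,
competing risks, or discrete failure times with heavy ties. Passing the
simulation checks therefore says nothing about those regimes; the
external-covariate and conditionally independent censoring assumptions are
taken as given.

## Baselines and metrics

The L2 baseline (`fit_l2_network()`) uses the identical architecture and
training protocol with mean-squared-error loss on raw $(x, y)$ rows, and
estimates the conditional distribution by shifting the empirical CDF of
training residuals to the fitted mean — valid only under i.i.d. errors
uncorrelated with the mean, which is the point of the Setup-2 comparison.
The Nadaraya–Watson baseline (`nw_cdf()`) uses a Gaussian product kernel (no
zero-mass failures in sparse regions, where a compact kernel would need
boundary handling) with per-dimension bandwidths $m \cdot \mathrm{sd}(x_d)
\cdot n^{-1/5}$ selected by 5-fold cross-validation on the mean squared
difference between held-out indicators $\mathbf 1(y \le y_g)$ and
$\widehat F(y_g \mid x)$ averaged over 21 response-grid points — "mean
squared error" for a CDF target is ambiguous between this discretised-CRPS
reading and regression MSE on $y$; we chose the former as the one that
actually scores the estimand, with ties going to the smaller bandwidth.

Censored-data scoring follows the standard inverse-probability-of-censoring
conventions: the censoring survival $\widehat G$ is a Kaplan–Meier fit to
$(y, 1 - \delta)$; the Brier score and binomial log-likelihood weight
subjects by $1/\widehat G(y_i^-)$ (the left limit, so a censoring event
never down-weights itself) or $1/\widehat G(t)$; terms with zero weight are
dropped with a warning. The time-dependent C-index counts comparable pairs
($\delta_i = 1$, $y_i < y_j$; tied event times excluded) and scores
predicted-survival ties as 1/2 — the convention under which an uninformative
predictor scores exactly 0.5. Integrated scores average the per-time curves
by the trapezoid rule over 100 equally spaced points between the test set's
minimum and maximum observed times; the integration resolution is a
package choice, so third-decimal agreement with other implementations of
integrated scores should not be expected.

## Problem sizes in the package's own checks

The package validates itself at deliberately moderate scale, chosen so the
whole suite replays comfortably on a laptop: the uncensored Setup-1/Setup-2
experiments use $n = 1000$ (split 500/500), 500-point test sets and 5
replications (10 in the reproduction script); the kernel comparison uses $n = 1000$ with 10 replications in
1-D and 5 in 2-D; constant-hazard parameter recovery uses $n = 2000$.
Replication $r$ of an experiment derives its seed as `seed + 1000 r`, so
adding replications never perturbs earlier ones; all generators are fully
seeded and reproducible. With 5 replications the Monte-Carlo standard error
of a coverage estimate at 0.9 is about 0.006 — well inside the tolerances
the checks use.

## Known limitations

* The expanded table grows as $O(n^2)$ rows; beyond a few thousand subjects
  memory and epoch time grow quickly. This is inherent to evaluating the
  likelihood on the observed-time grid.
* The conditional-mean estimator inherits the $1/n$ mass at $t_1$ and the
  (small) missing mass above $t_m$, giving a slight downward bias that
  vanishes only as $n$ grows.
* Quantiles are grid-valued: a predictive interval endpoint is always an
  observed training response.
* Single fits are deterministic given the seed, but results do depend on
  the seed through the split and initialisation; swap-averaging halves, but
  does not remove, that variability.
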