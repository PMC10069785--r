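---
title: "Correcting regression models for covariate measurement error with iteratively reweighted Monte Carlo EM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting regression models for covariate measurement error with iteratively reweighted Monte Carlo EM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eivmcem)
```

## The problem

Covariates are often measured imprecisely: blood pressure fluctuates between
clinic visits, gridded temperature products carry interpolation error, bird
wing lengths differ between handlers. Fitting a regression as if the observed
covariate $W$ were the true covariate $X$ — the *naive* fit — attenuates
coefficients and understates uncertainty.

`eivmcem` implements a structural correction under the classical
additive error model
$$W = X + U, \qquad U \sim N(0, \Sigma_u), \quad U \perp X,$$
with $\Sigma_u$ **known** (estimated externally from replicate measurements or
validation data), and a parametric working distribution $f_X$ for the true
covariate, taken to be (multivariate) normal. Both assumptions are the price
of a likelihood-based correction; the robustness experiments below probe the
second one.

## The algorithm

Write $f_Y(y \mid x; \beta)$ for the response model. The observed-data
log-likelihood integrates over the latent covariate,
$$\ell(\beta) = \sum_i \log \int f_Y(y_i \mid x; \beta)\, f_U(w_i - x)\,
  f_X(x)\, dx,$$
which rarely has a closed form for non-Gaussian responses. The package
maximises it with an EM algorithm whose E-step is approximated by importance
sampling *from the measurement-error prior*:

1. Fit the naive model to get $\hat\beta^{[0]}$.
2. Draw $B$ error replicates $\tilde u^{(b)} \sim N(0, \Sigma_u)$ **once**
   and construct imputations $\tilde x^{(b)} = w - \tilde u^{(b)}$. These are
   never redrawn: conditional on them the procedure is an exact EM algorithm,
   so the observed-data log-likelihood ascends monotonically and
   convergence is stable.
3. E-step: update only the per-observation importance weights
   $$q_i^{(b)} \propto f_Y(y_i \mid \tilde x_i^{(b)}; \hat\beta)\,
     f_X(\tilde x_i^{(b)}),$$
   normalised over $b$ for each $i$. Because the proposal is the error
   distribution itself, its density cancels the $f_U(w - x)$ factor, leaving
   exactly the response likelihood times the covariate prior.
4. M-step: refit the wrapped estimator to the stacked $nB$-row data
   $\{(y, \tilde x^{(1)}), \dots, (y, \tilde x^{(B)})\}$ with observation
   weights $q_i^{(b)}$. Any weighted maximum- or penalised-likelihood fitter
   can be used unchanged, which is what makes the approach generic.
5. Repeat 3–4 until the coefficients stabilise.

The weights are normalised per observation: the observations are independent,
so the joint importance weight factorises, and the per-observation form is
also what the standard-error formula consumes. All weight arithmetic is done
on the log scale with per-row max subtraction — binomial and Poisson
densities underflow already at a few hundred observations otherwise.

**Convergence** is declared when
$\max_k |\beta_k^{new} - \beta_k| / \max(1, \max_k|\beta_k|) < \epsilon$,
with $\epsilon = 10^{-5}$ and at most 100 iterations by default. The
max-norm is relative so that the criterion is insensitive to coefficient
scale; the denominator is floored at 1 so near-zero coefficients do not make
it pathologically strict.

**The covariate prior** $f_X$ is initialised by moment correction
($\hat\mu_x = \bar w$, $\hat\Sigma_x = \widehat{\mathrm{cov}}(w) - \Sigma_u$,
eigenvalues floored at $10^{-6}$ of the trace so the density stays proper)
and, by default, re-estimated at every iteration as the weighted mean and
weighted maximum-likelihood covariance of the imputations. That update is the
exact M-step for normal prior parameters, so the joint log-likelihood keeps
its ascent guarantee; set `prior_update = FALSE` (optionally with an explicit
`prior`) to hold it fixed.

**Diagnostics.** The effective sample size
$\mathrm{ESS}_i = 1/\sum_b (q_i^{(b)})^2 \in [1, B]$ measures how well the
prior proposal matches the per-observation posterior; it is reported per
observation and as a mean. It decays as the error variance or the number of
contaminated covariates grows — with mean ESS well below $B/2$, increase `B`.
The observed-data log-likelihood is reported rather than the EM Q-function,
computed as the Monte Carlo marginal
$\sum_i \log\{B^{-1}\sum_b f_Y f_X\}$; the algebraically identical
"Q minus weight entropy" route is evaluated alongside and asserted to agree
to $10^{-8}$ as an internal consistency check.

## Standard errors

The complete-data information from the final weighted fit ignores the
uncertainty in $X$ and would understate the variance. The package uses the
missing-information (Louis) form: with per-observation, per-imputation
scores $s_{ib}$ and Jacobians $J_{ib}$ evaluated analytically at
$\hat\beta$,
$$I_W = -\sum_i \sum_b q_i^{(b)} J_{ib}
  - \sum_i \sum_b q_i^{(b)} s_{ib} s_{ib}^{\top}
  + \sum_i \bar s_i \bar s_i^{\top}, \qquad
  \bar s_i = \sum_b q_i^{(b)} s_{ib},$$
and $\widehat{\mathrm{Var}}(\hat\beta) = I_W^{-1}$, solved through a QR
factorisation rather than an explicit inverse. When $\Sigma_u = 0$ all
imputations coincide, the last two terms cancel exactly, and the naive
Fisher information is recovered. A non-positive-definite $I_W$ means the
Monte Carlo error dominates; the error message says to increase $B$ (values
of $B \ge 50$ have been stable in all our experiments). For the gaussian
family the dispersion is estimated by the weighted mean squared residual at
convergence and treated as fixed in $I_W$; for penalised fits the penalty
curvature is added to the complete-data term, giving coefficient-covariance
("Bayesian-style") confidence bands for smooths.

## Fitters

Everything above is generic over a *fitter contract* (`new_fitter()`):
a design builder, a weighted fit, a per-observation log density, and
analytic score/Jacobian functions. Three fitters ship with the package:

* **GLMs** (`fitter_glm()`): canonical-link gaussian, binomial, Poisson via
  iteratively reweighted least squares. Polynomial terms such as `I(w^2)`
  are rebuilt from each imputation on the raw scale — imputing a transformed
  covariate would be wrong.
* **Penalised-spline GAMs** (`fitter_gam()`): mgcv smooths. Smoothing
  parameters are re-selected by GCV on every weighted refit by default,
  mirroring a full penalised-likelihood refit; pass `sp` to freeze them
  (e.g. at the naive fit's values) — the choice is exposed because neither
  option is canonical. Within one EM run the stacked imputed data are fixed,
  so basis and knots are identical across iterations and coefficients are
  comparable.
* **Positive-binomial conditional likelihood** (`fitter_posbinomial()`), for
  closed-population capture–recapture with occasion-constant individual
  capture probabilities $p_i = \mathrm{logit}^{-1}(\eta_i)$, $\eta_i$ linear
  or a B-spline in one covariate. Newton iterations with analytic first and
  second derivatives (the score has the tidy form
  $c_i - \tau p_i / \{1 - (1-p_i)^\tau\}$, observed count minus conditional
  mean). Spline knots are placed at quantiles of the observed covariate and
  frozen, with boundary knots widened by four error standard deviations so
  imputations stay inside; points beyond the boundary are clamped.

## A worked example

```{r example}
set.seed(1)
n <- 800
x <- rnorm(n)                              # true covariate
w <- x + rnorm(n, sd = sqrt(0.25))         # observed with known error 0.25
y <- rbinom(n, 1, plogis(0.5 + x - 0.3 * x^2))
d <- data.frame(y = y, w = w)

naive <- glm(y ~ w + I(w^2), family = binomial(), data = d)
fit <- mcem_refit(d, y ~ w + I(w^2), family = "binomial",
                  error_cols = "w", sigma_u = 0.25, B = 50, seed = 1)
tidy(fit)
glance(fit)
round(coef(naive), 3)  # attenuated quadratic term
```

The corrected quadratic coefficient moves from the attenuated naive value
back toward the generating value $-0.3$, and the Louis standard errors are
wider than the naive ones — both effects of acknowledging that $X$ was never
observed.

## Point processes and capture–recapture

**Point processes.** `build_berman_turner()` re-expresses the Poisson
point-process likelihood as a weighted Poisson GLM: quadrature points on a
regular grid carry weight $|A|/n$, presence points are appended with weight
$\varepsilon = 10^{-6}$ and pseudo-response $1/\varepsilon$. `fit_ppm()`
wraps that GLM in the EM engine, with quadrature weights and importance
weights composing multiplicatively; `predict_intensity()` evaluates
scenario shifts (e.g. add 1 °C to a temperature layer before prediction).
Covariate values at distinct points are treated as independently
contaminated — no spatial error-correlation model is imposed — and covariate
lookup is nearest-cell. One numerical caveat matters: the importance weight
at a quadrature point carries a factor $e^{-w_j \lambda}$, which is faithful
to the point-process likelihood only when the expected number of points per
cell is small. Use a quadrature grid fine enough that $m/n \lesssim 0.01$
(a fine grid is required for the integral approximation anyway); on coarse
grids the corrected slope overshoots.

**Capture–recapture.** `fit_capture_mcem()` nests the positive-binomial
conditional likelihood in the EM engine and estimates abundance by the
importance-weighted Horvitz–Thompson estimator
$\hat N = \sum_i \sum_b q_i^{(b)} / \hat\pi_i^{(b)}$ with
$\hat\pi_i^{(b)} = 1 - (1 - \hat p_i^{(b)})^{\tau}$. Its standard error
combines the Horvitz–Thompson variance $\sum (1-\pi)/\pi^2$ with a
delta-method term through the Louis covariance; this Huggins-type form is
our own reconstruction of the abundance variance, and it conditions on the
converged weights. AIC is reported as $-2\hat\ell + 2\,\mathrm{edf}$ using
the observed-data log-likelihood and the penalised fit's effective degrees
of freedom, so smooth and linear capture curves can be compared.

## The synthetic study harness

`sim_design()` / `gen_dataset()` / `run_sim_study()` reproduce the designs
used throughout the tests:

* *Bias–coverage*: logistic-quadratic model
  $\mathrm{logit}\, P(Y=1) = 0.5 + X - 0.3 X^2$, $X \sim N(0,1)$, $n = 800$,
  classical error added at a grid of variances. The harness reports relative
  bias, RMSE and Wald coverage of the quadratic coefficient for the naive
  and corrected fits.
* *Prediction*: `prediction_rmse()` evaluates the linear predictor on fresh
  test data, optionally shifting the covariate by 0.5 units to mimic a
  changing-climate extrapolation. Both the mean squared error
  $\sum(\eta - \hat\eta)^2 / n^*$ and its square root are reported — the two
  conventions coexist in the literature, so both are labelled explicitly and
  comparisons in this package use the square-rooted version.
* *Robustness*: covariate generators for $(\chi^2_3 - 3)/6$ and a two-piece
  skew normal (with probability $\kappa^2/(\kappa^2+1)$ return
  $\kappa |Z|$, else $-|Z|/\kappa$), to study mis-specification of the
  normal working prior. The $\chi^2$ scaling is kept literal (variance
  $1/6$); `standardize = TRUE` rescales to unit variance — the division by 6
  rather than $\sqrt 6$ is unusual enough that both options are shipped and
  exercised in tests.

What the generators emulate — and what they do not: independent
observations, a single contaminated covariate with homoscedastic normal
error of exactly known variance, and a correctly specified response family.
Real data add correlated errors, unknown and heteroscedastic error
variances, and covariate distributions further from normal than the two
shipped alternatives; a passing test suite shows the estimator and its
implementation behave under the stated model, not that the correction is
automatic on any data set.

## Problem sizes, numerical choices, limitations

The package's own simulation checks run at $n = 800$ with $B = 50$ and
100 replicates for the coverage study, with smaller qualitative checks at
6–20 replicates; these sizes give Monte Carlo standard errors a few times
smaller than the effects being asserted. Degenerate inputs are handled
explicitly: $\Sigma_u = 0$ reproduces the naive fit exactly (coefficients,
standard errors, and log-likelihood up to the additive $\sum_i \log
f_X(w_i)$ term); $B = 1$ gives unit weights; a weight row that underflows
for every imputation raises an error naming the observation rather than
propagating NaN. Known limitations: estimation of $\Sigma_u$ itself is out
of scope; importance sampling from the prior degrades as the number of
contaminated covariates grows (watch the mean ESS); the positive-binomial
spline is an unpenalised regression spline (choose `spline_df` modestly);
and PPM windows are rectangles with nearest-cell covariate lookup.
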