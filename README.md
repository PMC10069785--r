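# eivmcem

Errors-in-variables regression via iteratively reweighted Monte Carlo EM.

## What problem this solves, and for whom

Epidemiologists, ecologists and other applied modellers routinely regress an
outcome on covariates that were measured imprecisely — clinic blood-pressure
readings, interpolated climate layers, field measurements of morphology.
Fitting the model to the noisy covariate *W* as if it were the true covariate
*X* (the "naive" fit) biases coefficients toward zero and understates
uncertainty. `eivmcem` corrects **any** regression model fitted by maximum or
penalised likelihood for **classical additive measurement error**

    W = X + U,   U ~ N(0, Σᵤ),  U ⊥ X,

with Σᵤ known (from replicate measurements or validation data) and a normal
structural model f_X for the true covariate.

## The algorithm

The observed-data log-likelihood ℓ(β) = Σᵢ log ∫ f_Y(yᵢ | x; β) f_U(wᵢ − x)
f_X(x) dx is maximised by a Monte Carlo EM scheme that needs nothing from the
underlying model except a *weighted* fitting routine G(y; x; q):

1. fit the naive model for starting values;
2. draw B imputations x̃⁽ᵇ⁾ = w − ũ⁽ᵇ⁾, ũ⁽ᵇ⁾ ~ N(0, Σᵤ), **once** (fixed for
   the whole run, so the procedure is an exact EM conditional on them);
3. E-step: update importance weights only,
   qᵢ⁽ᵇ⁾ ∝ f_Y(yᵢ | x̃ᵢ⁽ᵇ⁾; β̂) · f_X(x̃ᵢ⁽ᵇ⁾), normalised over b per
   observation;
4. M-step: refit G to the stacked nB-row data with weights qᵢ⁽ᵇ⁾;
5. iterate to convergence (default ε = 1e-5, B = 50).

Standard errors come from the missing-information (Louis) form of the
observed information, I_W = −ΣΣ qJ − ΣΣ q s sᵀ + Σ s̄ s̄ᵀ, built from analytic
per-observation scores and Jacobians and solved by QR. Importance-weight
quality is diagnosed by the effective sample size ESSᵢ = 1/Σ_b (qᵢ⁽ᵇ⁾)² ∈
[1, B].

Shipped fitters: canonical-link GLMs, penalised-spline GAMs (mgcv, smoothing
re-selected by GCV at each refit), Poisson point-process models via
Berman–Turner quadrature (`build_berman_turner()`, `fit_ppm()`,
`predict_intensity()` for covariate-shift scenarios), and closed-population
capture–recapture via a positive-binomial conditional likelihood with a
weighted Horvitz–Thompson abundance estimator (`fit_capture_mcem()`). The
simulation harness (`sim_design()`, `run_sim_study()`, `prediction_rmse()`)
reproduces the bias/coverage, prediction-shift and robustness experiments.

## Worked example

```r
library(eivmcem)
set.seed(1)
n <- 800
x <- rnorm(n)                          # true covariate (never observed)
w <- x + rnorm(n, sd = sqrt(0.25))     # observed with known error variance
y <- rbinom(n, 1, plogis(0.5 + x - 0.3 * x^2))
d <- data.frame(y = y, w = w)

round(coef(glm(y ~ w + I(w^2), binomial, d)), 3)
#> (Intercept)           w      I(w^2)
#>       0.424       0.666      -0.129

fit <- mcem_refit(d, y ~ w + I(w^2), family = "binomial",
                  error_cols = "w", sigma_u = 0.25, B = 50, seed = 1)
tidy(fit)
#> # A tibble: 3 × 7
#>   term        estimate std.error statistic  p.value conf.low conf.high
#> 1 (Intercept)    0.496    0.104       4.77 1.83e- 6    0.292    0.700
#> 2 w              0.865    0.104       8.33 7.88e-17    0.661    1.07
#> 3 I(w^2)        -0.250    0.0825     -3.03 2.47e- 3   -0.412   -0.0881
glance(fit)
#> # A tibble: 1 × 8
#>   logLik   AIC   edf ess_mean n_iter converged  nobs     B
#> 1 -1745. 3495.     3     41.9     12 TRUE        800    50
```

The generating coefficients were (0.5, 1, −0.3). The naive quadratic term is
attenuated by more than half (−0.129); the corrected fit recovers −0.250 with
a standard error that honestly reflects the unobserved covariate, and the
mean effective sample size (41.9 of B = 50) says the importance weights are
healthy. `autoplot(fit)` shows the EM log-likelihood ascent and coefficient
trace; `eiv_refit()`/`eiv_summarize()` run the same workflow from a CSV plus
a YAML/JSON config and write JSON/CSV results (a thin command-line wrapper
lives in `inst/cli/eivfit.R`).

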