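test_that("with zero error variance the corrected fit collapses to the naive fit", {
  d <- make_logistic_data(n = 200, sigma_u2 = 0.25, seed = 10)
  nv <- glm(y ~ w + I(w^2), family = binomial(), data = d,
            control = glm.control(epsilon = 1e-12))
  fit <- mcem_refit(d[c("y", "w")], y ~ w + I(w^2), family = "binomial",
                    error_cols = "w", sigma_u = 0, B = 15, seed = 4)
  expect_equal(unname(fit$coefficients), unname(coef(nv)), tolerance = 1e-8)
  X <- model.matrix(nv)
  mu <- plogis(drop(X %*% coef(nv)))
  se_naive <- sqrt(diag(solve(crossprod(X, X * (mu * (1 - mu))))))
  expect_equal(unname(fit$se), unname(se_naive), tolerance = 1e-8)
  prior_part <- sum(dnorm(d$w, fit$prior$mean, sqrt(fit$prior$cov[1, 1]),
                          log = TRUE))
  expect_equal(fit$loglik - prior_part, as.numeric(logLik(nv)),
               tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("results are bitwise reproducible under the same seed", {
  d <- make_logistic_data(n = 150, sigma_u2 = 0.3, seed = 6)
  f1 <- mcem_refit(d[c("y", "w")], y ~ w + I(w^2), family = "binomial",
                   error_cols = "w", sigma_u = 0.3, B = 20, seed = 17)
  f2 <- mcem_refit(d[c("y", "w")], y ~ w + I(w^2), family = "binomial",
                   error_cols = "w", sigma_u = 0.3, B = 20, seed = 17)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$se, f2$se)
  expect_identical(f1$trace, f2$trace)
})

test_that("the observed log-likelihood ascends over EM iterations", {
  for (s in 1:3) {
    d <- make_logistic_data(n = 150, sigma_u2 = 0.4, seed = 20 + s)
    fit <- mcem_refit(d[c("y", "w")], y ~ w + I(w^2), family = "binomial",
                      error_cols = "w", sigma_u = 0.4, B = 25, seed = s)
    expect_true(all(diff(fit$trace$loglik) > -1e-6))
  }
})

test_that("the M-step equals the weighted stacked refit and its degenerate limits", {
  d <- make_logistic_data(n = 50, sigma_u2 = 0.25, seed = 30)
  fitter <- fitter_glm(~ w + I(w^2), d["w"], family = "binomial")
  spec <- me_spec("w", 0.25)

  # B = 1 with unit weights: unweighted fit on the single imputation
  imps1 <- draw_imputations(as.matrix(d["w"]), spec, B = 1, seed = 2)
  q1 <- manual_weights(matrix(1, 50, 1))
  ms <- m_step(fitter, d$y, d["w"], imps1, q1)
  direct <- glm(d$y ~ x + I(x^2), family = binomial(),
                data = data.frame(x = as.numeric(imps1$values[[1]])))
  expect_equal(unname(ms$beta), unname(coef(direct)), tolerance = 1e-8)

  # zero error: equals the naive fit regardless of B
  imps0 <- draw_imputations(as.matrix(d["w"]), me_spec("w", 0), B = 8, seed = 2)
  q0 <- manual_weights(matrix(1, 50, 8))
  ms0 <- m_step(fitter, d$y, d["w"], imps0, q0)
  nv <- glm(y ~ w + I(w^2), family = binomial(), data = d,
            control = glm.control(epsilon = 1e-12))
  expect_equal(unname(ms0$beta), unname(coef(nv)), tolerance = 1e-8)
})

test_that("mean ESS falls as the error variance and number of noisy covariates grow", {
  set.seed(55)
  grid <- c(0.1, 0.4, 0.8, 1.2)
  mean_ess <- sapply(grid, function(s2) {
    vals <- replicate(8, {
      r <- sample.int(10000, 1)
      d <- make_logistic_data(n = 200, sigma_u2 = s2, seed = r)
      fit <- suppressWarnings(
        mcem_refit(d[c("y", "w")], y ~ w + I(w^2), family = "binomial",
                   error_cols = "w", sigma_u = s2, B = 30,
                   seed = r, max_iter = 40))
      fit$ess_mean
    })
    mean(vals)
  })
  slope <- coef(lm(mean_ess ~ grid))[2]
  expect_lt(slope, 0)

  # two contaminated covariates deplete the ESS faster than one
  set.seed(77)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.3 + x1 - 0.5 * x2))
  dd <- data.frame(y = y,
                   w1 = x1 + rnorm(n, sd = sqrt(0.4)),
                   w2 = x2 + rnorm(n, sd = sqrt(0.4)))
  f1 <- mcem_refit(dd, y ~ w1 + w2, family = "binomial", error_cols = "w1",
                   sigma_u = 0.4, B = 30, seed = 5, max_iter = 40)
  f2 <- mcem_refit(dd, y ~ w1 + w2, family = "binomial",
                   error_cols = c("w1", "w2"), sigma_u = 0.4, B = 30,
                   seed = 5, max_iter = 40)
  expect_lt(f2$ess_mean, f1$ess_mean)
})

test_that("estimation error shrinks with sample size (consistency behaviour)", {
  errs <- sapply(c(800, 3200), function(n) {
    e <- sapply(1:8, function(r) {
      d <- make_logistic_data(n = n, sigma_u2 = 0.25, seed = 400 + r)
      fit <- mcem_refit(d[c("y", "w")], y ~ w + I(w^2), family = "binomial",
                        error_cols = "w", sigma_u = 0.25, B = 50,
                        seed = 400 + r, max_iter = 60)
      abs(fit$coefficients[3] - (-0.3))
    })
    median(e)
  })
  expect_lt(errs[2], errs[1])
})

test_that("a fixed prior can be supplied and is respected", {
  d <- make_logistic_data(n = 120, sigma_u2 = 0.25, seed = 44)
  pr <- prior_spec(0, 1)
  fit <- mcem_refit(d[c("y", "w")], y ~ w + I(w^2), family = "binomial",
                    error_cols = "w", sigma_u = 0.25, B = 20, seed = 3,
                    prior = pr, prior_update = FALSE)
  expect_equal(fit$prior$mean, 0)
  expect_equal(fit$prior$cov[1, 1], 1)
})

test_that("hitting max_iter warns and flags non-convergence", {
  d <- make_logistic_data(n = 150, sigma_u2 = 0.5, seed = 48)
  expect_warning(
    fit <- mcem_refit(d[c("y", "w")], y ~ w + I(w^2), family = "binomial",
                      error_cols = "w", sigma_u = 0.5, B = 20, seed = 3,
                      max_iter = 2),
    "did not converge")
  expect_false(fit$converged)
  expect_equal(fit$n_iter, 2L)
})
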