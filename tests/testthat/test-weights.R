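test_that("identical imputations give uniform weights; B = 1 gives weight one", {
  d <- make_logistic_data(n = 40, sigma_u2 = 0, seed = 2)
  fitter <- fitter_glm(~ w + I(w^2), d, family = "binomial")
  spec0 <- me_spec("w", 0)
  imps <- draw_imputations(as.matrix(d["w"]), spec0, B = 6, seed = 1)
  pr <- prior_spec(0, 1)
  q <- compute_importance_weights(d$y, imps, fitter, pr, c(0.4, 0.9, -0.2),
                                  data = d[c("w", "x")])
  expect_equal(unclass(q), matrix(1 / 6, 40, 6), tolerance = 1e-12)

  imps1 <- draw_imputations(as.matrix(d["w"]), me_spec("w", 0.3), B = 1, seed = 1)
  q1 <- compute_importance_weights(d$y, imps1, fitter, pr, c(0.4, 0.9, -0.2),
                                   data = d[c("w", "x")])
  expect_equal(unclass(q1), matrix(1, 40, 1))
})

test_that("weights match a hand evaluation of the importance-weight formula", {
  # one observation, two imputed atoms x = 0 and x = 1, beta = (0, 1),
  # y = 1 under a logit model, prior N(0, 1)
  fitter <- fitter_glm(~x, data.frame(x = 0), family = "binomial")
  imps <- manual_imps(list(matrix(0), matrix(1)))
  pr <- prior_spec(0, 1)
  q <- compute_importance_weights(1, imps, fitter, pr, c(0, 1),
                                  data = data.frame(x = 0))
  t1 <- plogis(0) * dnorm(0)        # f_Y(1|0) f_X(0)
  t2 <- plogis(1) * dnorm(1)        # f_Y(1|1) f_X(1)
  expect_equal(unclass(q)[1, ], c(t1, t2) / (t1 + t2), tolerance = 1e-10)
  expect_equal(unclass(q)[1, 1], 0.530, tolerance = 5e-4)
})

test_that("every weight row sums to one and stays finite under extreme scales", {
  d <- make_logistic_data(n = 200, sigma_u2 = 0.5, seed = 3)
  fitter <- fitter_glm(~ w + I(w^2), d, family = "binomial")
  imps <- draw_imputations(as.matrix(d["w"]), me_spec("w", 0.5), B = 25, seed = 9)
  pr <- prior_spec(0, 1)
  for (beta in list(c(0.5, 1, -0.3), c(-8, 12, -5))) {
    q <- compute_importance_weights(d$y, imps, fitter, pr, beta,
                                    data = d[c("w", "x")])
    expect_true(all(is.finite(q)))
    expect_true(all(abs(rowSums(q) - 1) < 1e-12))
    expect_true(all(q >= 0))
  }
})

test_that("effective sample size follows the inverse-sum-of-squares formula", {
  B <- 8
  expect_equal(effective_sample_size(manual_weights(matrix(1, 3, B)))$per_obs,
               rep(B, 3))
  q_deg <- manual_weights(matrix(c(1, rep(0, B - 1)), 1, B))
  expect_equal(effective_sample_size(q_deg)$per_obs, 1)
  q3 <- manual_weights(matrix(c(0.5, 0.25, 0.25), 1, 3))
  expect_equal(effective_sample_size(q3)$per_obs, 1 / 0.375, tolerance = 1e-10)
  # bounds hold on random rows
  set.seed(4)
  qr_ <- manual_weights(matrix(runif(50 * 12), 50, 12))
  ess <- effective_sample_size(qr_)$per_obs
  expect_true(all(ess >= 1 - 1e-12 & ess <= 12 + 1e-12))
})

test_that("prior update reduces to the replicate moments in the limits", {
  set.seed(7)
  x1 <- matrix(rnorm(50, 2, 1), ncol = 1, dimnames = list(NULL, "w"))
  imps <- manual_imps(list(x1), cols = "w")
  pr <- update_prior(imps, manual_weights(matrix(1, 50, 1)))
  expect_equal(pr$mean, mean(x1))
  expect_equal(pr$cov[1, 1], var(x1[, 1]) * 49 / 50, tolerance = 1e-10)

  # all weight on replicate 2 -> moments of that replicate alone
  x2 <- matrix(rnorm(50, -1, 2), ncol = 1, dimnames = list(NULL, "w"))
  imps2 <- manual_imps(list(x1, x2), cols = "w")
  q <- manual_weights(cbind(rep(1e-14, 50), rep(1, 50)))
  pr2 <- update_prior(imps2, q)
  expect_equal(pr2$mean, mean(x2), tolerance = 1e-6)
})

test_that("prior update recovers the generating covariate moments", {
  set.seed(12)
  n <- 500
  x <- rnorm(n, 2, sqrt(1.5))
  w <- x + rnorm(n, sd = 0.5)
  spec <- me_spec("w", 0.25)
  imps <- draw_imputations(matrix(w, ncol = 1, dimnames = list(NULL, "w")),
                           spec, B = 100, seed = 3)
  q <- manual_weights(matrix(1, n, 100))
  pr <- update_prior(imps, q)
  expect_lt(abs(pr$mean - 2), 3 * sqrt((1.5 + 0.5) / n))
})

test_that("observed log-likelihood collapses correctly when there is no error", {
  d <- make_logistic_data(n = 60, sigma_u2 = 0, seed = 5)
  fitter <- fitter_glm(~ w + I(w^2), d["w"], family = "binomial")
  nv <- glm(y ~ w + I(w^2), family = binomial(), data = d)
  imps <- draw_imputations(as.matrix(d["w"]), me_spec("w", 0), B = 4, seed = 1)
  pr <- prior_spec(0.1, 1.3)
  ll <- observed_loglik(d$y, imps, fitter, pr, coef(nv), data = d["w"])
  expect_equal(ll, as.numeric(logLik(nv)) + sum(dnorm(d$w, 0.1, sqrt(1.3), log = TRUE)),
               tolerance = 1e-8)
})

test_that("observed log-likelihood matches a conjugate closed form at large B", {
  # y = beta x + e with x ~ N(mu, sx2), w = x + u: (y, w) are jointly normal,
  # so the marginal likelihood of (y | w) has a closed form
  set.seed(21)
  n <- 40; beta <- 0.8; sx2 <- 1; su2 <- 0.25; se2 <- 0.25; mu <- 0.5
  x <- rnorm(n, mu, sqrt(sx2))
  w <- x + rnorm(n, sd = sqrt(su2))
  y <- beta * x + rnorm(n, sd = sqrt(se2))
  d <- data.frame(w = w)
  fitter <- fitter_glm(~ w - 1, d, family = "gaussian", dispersion = se2)
  spec <- me_spec("w", su2)
  imps <- draw_imputations(as.matrix(d), spec, B = 4000, seed = 8)
  pr <- prior_spec(mu, sx2)
  ll <- observed_loglik(y, imps, fitter, pr, beta,
                        extra = list(dispersion = se2), data = d)
  # (1/B) sum_b f_Y(y|x_b) f_X(x_b), x_b = w - u, u ~ f_U, estimates
  # int f_Y(y|x) f_X(x) f_U(w - x) dx = f_{Y,W}(y, w): the exact bivariate
  # normal joint density is the oracle
  expect_equal(ll, sum(mvtnorm::dmvnorm(
    cbind(y, w), mean = c(beta * mu, mu),
    sigma = matrix(c(beta^2 * sx2 + se2, beta * sx2,
                     beta * sx2, sx2 + su2), 2), log = TRUE)),
    tolerance = 0.05 * abs(ll))
})

test_that("weight computation reports hopeless underflow rather than NaN", {
  fitter <- fitter_glm(~x, data.frame(x = 0), family = "poisson")
  imps <- manual_imps(list(matrix(-2000), matrix(-2000)))
  pr <- prior_spec(0, 1)
  expect_error(
    compute_importance_weights(5, imps, fitter, pr, c(0, 1),
                               data = data.frame(x = 0)),
    "underflow")
})
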