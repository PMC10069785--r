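test_that("analytic scores and Jacobians match finite differences", {
  set.seed(9)
  n <- 12
  d <- data.frame(w = rnorm(n))
  for (fam in c("gaussian", "binomial", "poisson")) {
    y <- switch(fam,
                gaussian = rnorm(n, 0.5 + d$w),
                binomial = rbinom(n, 1, plogis(0.5 + d$w)),
                poisson = rpois(n, exp(0.5 + d$w)))
    fitter <- fitter_glm(~w, d, family = fam, dispersion = 1)
    D <- fitter$design(d)
    beta <- c(0.3, 0.7)
    extra <- list(dispersion = 1)
    s <- fitter$score(y, D, beta, extra)
    J <- fitter$jacobian(y, D, beta, extra)
    for (i in c(1, 5, n)) {
      fi <- function(b) fitter$log_density(y, D, b, extra)[i]
      expect_equal(unname(s[i, ]), numDeriv::grad(fi, beta), tolerance = 1e-6)
      expect_equal(J[, , i], numDeriv::hessian(fi, beta), tolerance = 1e-5)
    }
  }
})

test_that("logistic score at beta = 0 is (y - 1/2) x", {
  d <- data.frame(w = c(-1, 0, 2))
  fitter <- fitter_glm(~w, d, family = "binomial")
  D <- fitter$design(d)
  y <- c(1, 0, 1)
  s <- fitter$score(y, D, c(0, 0), NULL)
  expect_equal(s, D * (y - 0.5), ignore_attr = TRUE)
})

test_that("the weighted score vanishes at the M-step maximiser", {
  d <- make_logistic_data(n = 250, sigma_u2 = 0.25, seed = 31)
  fitter <- fitter_glm(~ w + I(w^2), d["w"], family = "binomial")
  spec <- me_spec("w", 0.25)
  imps <- draw_imputations(as.matrix(d["w"]), spec, B = 30, seed = 2)
  set.seed(3)
  q <- manual_weights(matrix(runif(250 * 30, 0.2, 1), 250, 30))
  ms <- m_step(fitter, d$y, d["w"], imps, q)
  ss <- per_obs_score_jacobian(fitter, d$y, imps, ms$beta, data = d["w"])
  total <- numeric(ss$d)
  for (k in seq_len(ss$d)) {
    total[k] <- sum(matrix(ss$scores[, , k], ss$n, ss$B) * unclass(q))
  }
  expect_lt(max(abs(total)), 1e-5)
})

test_that("with no measurement error the Louis information is the naive Fisher information", {
  d <- make_logistic_data(n = 150, sigma_u2 = 0.25, seed = 32)
  fitter <- fitter_glm(~ w + I(w^2), d["w"], family = "binomial")
  nv <- glm(y ~ w + I(w^2), family = binomial(), data = d,
            control = glm.control(epsilon = 1e-12))
  beta <- coef(nv)
  imps <- draw_imputations(as.matrix(d["w"]), me_spec("w", 0), B = 6, seed = 1)
  ss <- per_obs_score_jacobian(fitter, d$y, imps, beta, data = d["w"])
  q <- manual_weights(matrix(1, 150, 6))
  IW <- louis_information(ss, q)
  # all imputations identical: missing-information terms cancel exactly
  D <- fitter$design(d["w"])
  mu <- plogis(drop(D %*% beta))
  fisher <- crossprod(D, D * (mu * (1 - mu)))
  expect_equal(IW, fisher, ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(solve(IW), vcov(nv), ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("Louis information matches the conjugate closed-form observed information", {
  # gaussian response, known dispersion, fixed true prior: the observed-data
  # likelihood sum log f(y|w; beta) is available in closed form, so its
  # curvature at beta-hat is an exact oracle for the Monte Carlo Eq-form
  set.seed(61)
  n <- 80; beta_t <- 0.8; sx2 <- 1; su2 <- 0.3; se2 <- 0.25; mu <- 0
  x <- rnorm(n, mu, sqrt(sx2))
  w <- x + rnorm(n, sd = sqrt(su2))
  y <- beta_t * x + rnorm(n, sd = sqrt(se2))
  d <- data.frame(w = w)
  fitter <- fitter_glm(~ w - 1, d, family = "gaussian", dispersion = se2)
  spec <- me_spec("w", su2)
  fit <- run_mcem(fitter, y, d, spec, B = 2000, seed = 12,
                  prior = prior_spec(mu, sx2), prior_update = FALSE)
  bh <- fit$coefficients

  ll_obs <- function(b) {
    S12 <- b * sx2
    sum(mvtnorm::dmvnorm(cbind(y, w), mean = c(b * mu, mu),
                         sigma = matrix(c(b^2 * sx2 + se2, S12,
                                          S12, sx2 + su2), 2), log = TRUE))
  }
  I_exact <- -numDeriv::hessian(function(b) ll_obs(b), bh)[1, 1]
  expect_equal(fit$information[1, 1], I_exact,
               tolerance = 0.02 * abs(I_exact))
})

test_that("covariance solve agrees with a dense inverse and flags problems", {
  expect_equal(coefficient_covariance(diag(2))$se, c(1, 1))
  I2 <- diag(c(4, 25))
  expect_equal(coefficient_covariance(I2)$se, c(0.5, 0.2))
  set.seed(13)
  for (r in 1:5) {
    A <- crossprod(matrix(rnorm(25), 5))
    A <- A + diag(5) * 0.1
    expect_equal(coefficient_covariance(A)$covariance, solve(A),
                 tolerance = 1e-10)
  }
  expect_error(coefficient_covariance(diag(c(1, -2))), "increase B")
  expect_warning(coefficient_covariance(diag(c(1, 1e-14))), "ill-conditioned")
})

test_that("corrected standard errors exceed the naive ones under measurement error", {
  bigger <- sapply(1:10, function(r) {
    d <- make_logistic_data(n = 300, sigma_u2 = 0.4, seed = 500 + r)
    nv <- glm(y ~ w + I(w^2), family = binomial(), data = d)
    fit <- mcem_refit(d[c("y", "w")], y ~ w + I(w^2), family = "binomial",
                      error_cols = "w", sigma_u = 0.4, B = 40,
                      seed = 500 + r, max_iter = 60)
    fit$se[3] >= sqrt(diag(vcov(nv)))[3]
  })
  expect_gte(mean(bigger), 0.9)
})

test_that("Wald intervals use the requested confidence level", {
  vc <- coefficient_covariance(diag(c(4, 25)), beta = c(1, -1), level = 0.9)
  z <- qnorm(0.95)
  expect_equal(vc$ci[, "lower"], c(1, -1) - z * c(0.5, 0.2))
  expect_equal(vc$ci[, "upper"], c(1, -1) + z * c(0.5, 0.2))
})
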