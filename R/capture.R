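#' Probability of ever being captured
#'
#' For an individual with occasion-constant capture probability `p` over
#' `tau` occasions, the inclusion probability is `pi = 1 - (1 - p)^tau`.
#'
#' @param p Vector of per-occasion capture probabilities, strictly in (0, 1).
#' @param tau Number of capture occasions.
#' @return Vector of inclusion probabilities.
#' @export
capture_inclusion_prob <- function(p, tau) {
  if (any(p <= 0 | p >= 1)) stop("Capture probabilities must lie strictly in (0, 1).")
  if (tau < 1) stop("`tau` must be at least 1.")
  1 - (1 - p)^tau
}

#' Horvitz-Thompson population-size estimator
#'
#' Naive form `N = sum_i 1/pi_i`, or, after a measurement-error-corrected
#' fit, the importance-weighted form `N = sum_i sum_b q_i^(b) / pi_i^(b)`
#' where `pi_i^(b)` uses the capture probability evaluated at the `b`th
#' imputation. The returned standard error is the Horvitz-Thompson
#' (Huggins-type) component `sqrt(sum (1 - pi)/pi^2)` only; coefficient
#' uncertainty is added by the delta method inside [fit_capture_mcem()].
#'
#' @param pi Inclusion probabilities: a vector (naive) or an `n x B` matrix
#'   of per-imputation values.
#' @param weights `n x B` importance weights, required when `pi` is a
#'   matrix.
#' @return List with `N_hat` and `se`.
#' @export
horvitz_thompson <- function(pi, weights = NULL) {
  if (is.matrix(pi)) {
    if (is.null(weights)) stop("`weights` are required with per-imputation pi.")
    q <- unclass(weights)
    stopifnot(all(dim(q) == dim(pi)))
    if (any(pi <= 1e-10)) stop("Inclusion probabilities near zero; the estimator is unstable.")
    if (any(pi > 1 + 1e-12)) stop("Inclusion probabilities must be at most 1.")
    N_hat <- sum(q / pi)
    var_ht <- sum(q * (1 - pi) / pi^2)
  } else {
    if (any(pi <= 1e-10)) stop("Inclusion probabilities near zero; the estimator is unstable.")
    if (any(pi > 1 + 1e-12)) stop("Inclusion probabilities must be at most 1.")
    N_hat <- sum(1 / pi)
    var_ht <- sum((1 - pi) / pi^2)
  }
  list(N_hat = N_hat, se = sqrt(var_ht))
}

#' Naive conditional-likelihood capture-recapture fit
#'
#' Positive-binomial conditional likelihood on the observed covariate (no
#' measurement-error correction), with Horvitz-Thompson abundance. Abundance
#' uncertainty combines the Horvitz-Thompson variance with a delta-method
#' term for the coefficient uncertainty.
#'
#' @param histories `D x tau` 0/1 capture-history matrix.
#' @param covariate Individual covariate vector (length `D`).
#' @param spline_df `NULL` for a linear predictor, else B-spline basis size.
#' @return List of class `capture_fit`: `beta`, `se`, `p`, `pi`, `N_hat`,
#'   `N_se`, `loglik`, `aic`, `edf`.
#' @export
fit_capture_naive <- function(histories, covariate, spline_df = NULL) {
  H <- as.matrix(histories)
  tau <- ncol(H)
  if (tau < 2) stop("At least two capture occasions are required.")
  dat <- data.frame(x = as.numeric(covariate))
  fitter <- fitter_posbinomial(tau, "x", dat, spline_df = spline_df)
  D <- fitter$design(dat)
  cvec <- rowSums(H)
  fit <- fit_weighted_posbinomial(cvec, D, tau = tau)
  info <- -crossprod(D, D * posbinom_jac_eta(fit$linear_predictor, tau))
  vc <- coefficient_covariance(info, beta = fit$beta)
  pi <- capture_inclusion_prob(fit$p, tau)
  ht <- horvitz_thompson(pi)
  # delta-method term: dN/dbeta = -sum_i pi^-2 dpi/dbeta
  p <- fit$p
  dpi <- tau * (1 - p)^(tau - 1) * p * (1 - p)
  g <- -colSums(D * (dpi / pi^2))
  N_var <- ht$se^2 + drop(t(g) %*% vc$covariance %*% g)
  structure(list(beta = fit$beta, se = vc$se, covariance = vc$covariance,
                 p = p, pi = pi, N_hat = ht$N_hat, N_se = sqrt(N_var),
                 loglik = fit$loglik, edf = fit$edf,
                 aic = -2 * fit$loglik + 2 * fit$edf, tau = tau,
                 fitter = fitter),
            class = "capture_fit")
}

#' Capture-recapture abundance with a mismeasured individual covariate
#'
#' Nests the weighted positive-binomial conditional likelihood inside the
#' reweighted EM engine to correct for classical measurement error in the
#' individual covariate (e.g. wing length measured with known error
#' variance), then estimates abundance by the importance-weighted
#' Horvitz-Thompson estimator. The abundance standard error combines the
#' Horvitz-Thompson variance with a delta-method term through the Louis
#' coefficient covariance. AIC is `-2 * observed log-likelihood + 2 * edf`.
#'
#' @param histories `D x tau` 0/1 capture-history matrix, every row with at
#'   least one capture.
#' @param covariate Individual covariate vector (length `D`).
#' @param sigma_u Known measurement-error variance of the covariate.
#' @param spline_df `NULL` for a linear predictor; otherwise the B-spline
#'   basis dimension for a smooth capture-probability curve.
#' @param B,epsilon,max_iter,seed,... Passed to [run_mcem()].
#' @return An `mcem_fit` subclass `capture_mcem` with additional elements
#'   `N_hat`, `N_se`, `aic`, `tau`.
#' @export
fit_capture_mcem <- function(histories, covariate, sigma_u, spline_df = NULL,
                             B = 50, epsilon = 1e-5, max_iter = 100,
                             seed = 1L, ...) {
  H <- as.matrix(histories)
  tau <- ncol(H)
  if (tau < 2) stop("At least two capture occasions are required.")
  cvec <- rowSums(H)
  if (any(cvec < 1)) stop("Every individual must have at least one capture.")
  dat <- data.frame(x = as.numeric(covariate))
  spec <- me_spec("x", sigma_u)
  fitter <- fitter_posbinomial(tau, "x", dat, spline_df = spline_df,
                               boundary_pad = 4 * sqrt(max(sigma_u, var(dat$x))))
  out <- run_mcem(fitter, cvec, dat, spec, B = B, epsilon = epsilon,
                  max_iter = max_iter, seed = seed, ...)

  designs <- imputed_designs(fitter, dat, out$imputations)
  q <- unclass(out$weights)
  n <- nrow(q)
  pmat <- pimat <- matrix(NA_real_, n, out$B)
  g <- numeric(length(out$coefficients))
  for (b in seq_len(out$B)) {
    Db <- designs[[b]]
    p <- plogis(drop(Db %*% out$coefficients))
    pi_b <- 1 - (1 - p)^tau
    pmat[, b] <- p
    pimat[, b] <- pi_b
    dpi <- tau * (1 - p)^(tau - 1) * p * (1 - p)
    g <- g - colSums(Db * (q[, b] * dpi / pi_b^2))
  }
  ht <- horvitz_thompson(pimat, out$weights)
  N_var <- ht$se^2 + drop(t(g) %*% out$covariance %*% g)

  out$N_hat <- ht$N_hat
  out$N_se <- sqrt(N_var)
  out$aic <- -2 * out$loglik + 2 * out$edf
  out$tau <- tau
  out$capture_histories <- H
  class(out) <- c("capture_mcem", class(out))
  out
}

#' @export
print.capture_mcem <- function(x, ...) {
  NextMethod()
  cat(sprintf("\n  N-hat = %.2f (SE %.2f)   AIC = %.2f   (D = %d, tau = %d)\n",
              x$N_hat, x$N_se, x$aic, x$nobs, x$tau))
  invisible(x)
}
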