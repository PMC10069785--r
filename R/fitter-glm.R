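#' Construct a fitter contract
#'
#' A fitter bundles everything the reweighted EM engine needs from a weighted
#' maximum (or penalised) likelihood estimator: a design builder, a weighted
#' fit, the per-observation log response density, analytic score and Jacobian
#' (second-derivative) functions, and a linear-predictor method. Any model
#' satisfying this contract can be corrected for covariate measurement error
#' by [run_mcem()].
#'
#' @param design `function(data) -> D`: builds the fit-ready design (a model
#'   matrix, or the data frame itself for smoothers) from raw covariates.
#'   Polynomial/spline terms must be rebuilt here from the raw scale, so that
#'   imputations are never transformed twice.
#' @param fit `function(y, D, q) -> list(beta, linear_predictor, loglik, edf,
#'   converged, extra)`: weighted ML/penalised-likelihood fit. With uniform
#'   weights it must reproduce the unweighted estimate.
#' @param log_density `function(y, D, beta, extra) -> n-vector` of
#'   per-observation log-likelihood contributions (strictly greater than
#'   `-Inf` on the support).
#' @param score `function(y, D, beta, extra) -> n x d matrix` of gradients.
#' @param jacobian `function(y, D, beta, extra) -> d x d x n array` of
#'   second-derivative matrices.
#' @param predict `function(D, beta, extra) -> n-vector` linear predictor.
#' @param penalty_hessian Optional `function(extra) -> d x d` penalty
#'   curvature (for penalised fits); `NULL` for plain ML.
#' @param label Human-readable fitter description.
#' @return An object of class `eiv_fitter`.
#' @export
new_fitter <- function(design, fit, log_density, score, jacobian, predict,
                       penalty_hessian = NULL, label = "custom fitter") {
  structure(list(design = design, fit = fit, log_density = log_density,
                 score = score, jacobian = jacobian, predict = predict,
                 penalty_hessian = penalty_hessian, label = label),
            class = "eiv_fitter")
}

#' @export
print.eiv_fitter <- function(x, ...) {
  cat("<eiv_fitter>", x$label, "\n")
  invisible(x)
}

glm_family <- function(family) {
  if (is.character(family)) {
    family <- switch(family,
                     gaussian = gaussian(),
                     binomial = binomial(),
                     poisson  = poisson(),
                     stop("Unsupported family '", family,
                          "'; use gaussian, binomial or poisson."))
  }
  if (!family$family %in% c("gaussian", "binomial", "poisson") ||
      family$link != switch(family$family, gaussian = "identity",
                            binomial = "logit", poisson = "log")) {
    stop("Only canonical-link gaussian, binomial and poisson families are supported.")
  }
  family
}

glm_logdens <- function(y, eta, family, dispersion = 1) {
  switch(family,
         gaussian = dnorm(y, mean = eta, sd = sqrt(dispersion), log = TRUE),
         binomial = dbinom(y, size = 1, prob = plogis(eta), log = TRUE),
         poisson  = dpois(y, lambda = exp(eta), log = TRUE))
}

glm_mu <- function(eta, family) {
  switch(family, gaussian = eta, binomial = plogis(eta), poisson = exp(eta))
}

# dmu/deta for the canonical link (= variance function)
glm_dmu <- function(mu, family) {
  switch(family, gaussian = rep(1, length(mu)), binomial = mu * (1 - mu),
         poisson = mu)
}

#' Weighted exponential-family GLM fit
#'
#' Maximises `sum_i q_i log f_Y(y_i | x_i; beta)` by iteratively reweighted
#' least squares ([stats::glm.fit()]), with `q` acting as prior observation
#' weights (distinct from binomial trial counts). For the gaussian family the
#' dispersion is the weighted mean squared residual (maximum-likelihood
#' form) unless supplied.
#'
#' @param y Response vector.
#' @param X Design matrix (full column rank on the weighted support).
#' @param q Non-negative observation weights, not all zero.
#' @param family `"gaussian"`, `"binomial"` or `"poisson"` (canonical links).
#' @param dispersion Fixed gaussian dispersion; `NULL` to estimate.
#' @return List with `beta`, `linear_predictor`, `loglik` (weighted),
#'   `edf`, `converged`, `extra` (carries `dispersion`).
#' @export
fit_weighted_glm <- function(y, X, q, family = "binomial", dispersion = NULL) {
  fam <- glm_family(family)
  X <- as.matrix(X)
  q <- as.numeric(q)
  if (any(q < 0) || all(q == 0)) stop("Weights must be non-negative and not all zero.")
  keep <- q > 0
  if (qr(X[keep, , drop = FALSE] * sqrt(q[keep]))$rank < ncol(X)) {
    stop("Design matrix is rank deficient on the weighted support.")
  }
  fit <- suppressWarnings(
    glm.fit(X, y, weights = q, family = fam,
            control = list(maxit = 50, epsilon = 1e-10))
  )
  if (!fit$converged) {
    stop("IRLS failed to converge in 50 steps (final deviance ",
         format(fit$deviance), "); possible separation or an ill-posed fit.")
  }
  beta <- coef(fit)
  if (any(!is.finite(beta))) stop("Non-finite coefficients from weighted GLM fit.")
  eta <- drop(X %*% beta)
  phi <- 1
  if (fam$family == "gaussian") {
    phi <- dispersion %||% (sum(q * (y - eta)^2) / sum(q))
  }
  list(beta = beta,
       linear_predictor = eta,
       loglik = sum(q * glm_logdens(y, eta, fam$family, phi)),
       edf = ncol(X),
       converged = TRUE,
       extra = list(dispersion = phi, family = fam$family))
}

#' GLM fitter contract for the EM engine
#'
#' Wraps [fit_weighted_glm()] as a fitter contract. The design matrix is
#' built by [stats::model.matrix()] from a one-sided formula over the raw
#' covariates, so polynomial terms such as `I(w^2)` or `poly(w, 2, raw =
#' TRUE)` are recomputed from every imputation.
#'
#' @param formula One-sided formula over covariate columns, e.g.
#'   `~ w + I(w^2) + z`.
#' @param data Template covariate data frame (used to fix factor contrasts).
#' @param family `"gaussian"`, `"binomial"` or `"poisson"`.
#' @param dispersion Fixed gaussian dispersion, `NULL` to estimate per fit.
#' @return An [new_fitter()] object.
#' @export
fitter_glm <- function(formula, data, family = "binomial", dispersion = NULL) {
  fam <- glm_family(family)$family
  tt <- delete.response(terms(formula, data = data))

  design <- function(data) model.matrix(tt, data)
  new_fitter(
    design = design,
    fit = function(y, D, q) fit_weighted_glm(y, D, q, fam, dispersion),
    log_density = function(y, D, beta, extra) {
      phi <- if (fam == "gaussian") (extra$dispersion %||% dispersion %||% 1) else 1
      glm_logdens(y, drop(D %*% beta), fam, phi)
    },
    score = function(y, D, beta, extra) {
      phi <- if (fam == "gaussian") (extra$dispersion %||% dispersion %||% 1) else 1
      mu <- glm_mu(drop(D %*% beta), fam)
      D * ((y - mu) / phi)
    },
    jacobian = function(y, D, beta, extra) {
      phi <- if (fam == "gaussian") (extra$dispersion %||% dispersion %||% 1) else 1
      mu <- glm_mu(drop(D %*% beta), fam)
      v <- glm_dmu(mu, fam) / phi
      d <- ncol(D)
      arr <- array(0, c(d, d, nrow(D)))
      for (j in seq_len(d)) {
        for (k in seq_len(j)) {
          val <- -v * D[, j] * D[, k]
          arr[j, k, ] <- val
          arr[k, j, ] <- val
        }
      }
      arr
    },
    predict = function(D, beta, extra = NULL) drop(D %*% beta),
    label = paste0("weighted GLM (", fam, ", canonical link)")
  )
}
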