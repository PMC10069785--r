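#' Per-observation, per-imputation scores and Jacobians
#'
#' Evaluates the analytic gradient `s(y_i, x_i^(b); beta)` and Jacobian
#' `J(y_i, x_i^(b); beta)` of the per-observation log-likelihood at every
#' imputation, the raw material for the Louis observed information. Any fixed
#' base weights (e.g. quadrature weights) scale both, since they multiply the
#' log-likelihood contribution.
#'
#' @inheritParams compute_importance_weights
#' @param data Raw covariate data frame (used when `designs` is `NULL`).
#' @return List of class `score_set` with `scores` (`n x B x d` array) and
#'   `jacobians` (`n x B x d x d` array).
#' @export
per_obs_score_jacobian <- function(fitter, y, imps, beta, extra = NULL,
                                   base_weights = NULL, designs = NULL,
                                   data = NULL) {
  if (is.null(designs)) {
    if (is.null(data)) stop("Supply either `designs` or `data`.")
    designs <- imputed_designs(fitter, data, imps)
  }
  n <- imps$n
  B <- imps$B
  d <- length(beta)
  bw <- base_weights %||% rep(1, n)
  scores <- array(NA_real_, c(n, B, d))
  jac <- array(NA_real_, c(n, B, d, d))
  for (b in seq_len(B)) {
    s <- fitter$score(y, designs[[b]], beta, extra)
    scores[, b, ] <- s * bw
    J <- fitter$jacobian(y, designs[[b]], beta, extra)  # d x d x n
    jac[, b, , ] <- aperm(J, c(3, 1, 2)) * bw
  }
  if (any(!is.finite(scores)) || any(!is.finite(jac))) {
    stop("Non-finite score or Jacobian entries at the supplied coefficients.")
  }
  structure(list(scores = scores, jacobians = jac, n = n, B = B, d = d),
            class = "score_set")
}

#' Louis observed information
#'
#' Monte Carlo form of the missing-information principle: the observed
#' information for `beta` is the weighted complete-data information minus the
#' missing information,
#' \deqn{I_W = -\sum_i \sum_b q_i^{(b)} J_{ib}
#'       - \sum_i \sum_b q_i^{(b)} s_{ib} s_{ib}^T
#'       + \sum_i \bar{s}_i \bar{s}_i^T,}
#' with \eqn{\bar{s}_i = \sum_b q_i^{(b)} s_{ib}}. For penalised fits the
#' penalty curvature is added to the first (complete-data) term. When all
#' imputations coincide (no measurement error) the second and third terms
#' cancel exactly and the naive Fisher information is recovered.
#'
#' @param scoreset A [per_obs_score_jacobian()] result at the converged
#'   coefficients.
#' @param weights The converged `n x B` importance-weight matrix.
#' @param penalty Optional `d x d` penalty Hessian (penalised likelihood).
#' @return Symmetric `d x d` information matrix.
#' @export
louis_information <- function(scoreset, weights, penalty = NULL) {
  q <- unclass(weights)
  n <- scoreset$n; B <- scoreset$B; d <- scoreset$d
  stopifnot(nrow(q) == n, ncol(q) == B)
  qv <- as.vector(q)                         # (i, b) in column-major order

  # complete-data term: -sum_ib q_ib J_ib
  Jm <- matrix(scoreset$jacobians, n * B, d * d)
  term1 <- -matrix(colSums(Jm * qv), d, d)

  # missing-information term: -sum_ib q_ib s_ib s_ib^T
  Sm <- matrix(scoreset$scores, n * B, d)
  term2 <- -crossprod(Sm * sqrt(qv))

  # recovered term: + sum_i sbar_i sbar_i^T
  sbar <- matrix(0, n, d)
  for (k in seq_len(d)) {
    sbar[, k] <- rowSums(matrix(scoreset$scores[, , k], n, B) * q)
  }
  term3 <- crossprod(sbar)

  IW <- term1 + term2 + term3
  if (!is.null(penalty)) IW <- IW + penalty
  (IW + t(IW)) / 2
}

#' Coefficient covariance, standard errors and Wald intervals
#'
#' Inverts the Louis information through its QR factorisation (no explicit
#' inverse), returning the covariance, standard errors, and Wald confidence
#' intervals `beta +/- z * SE`.
#'
#' @param I_W Positive-definite information matrix.
#' @param beta Optional coefficient vector (enables the CI columns).
#' @param level Confidence level (default 0.95).
#' @return List with `covariance`, `se`, and (when `beta` is given) a
#'   `ci` matrix with columns `lower`, `upper`.
#' @export
coefficient_covariance <- function(I_W, beta = NULL, level = 0.95) {
  I_W <- as.matrix(I_W)
  d <- ncol(I_W)
  ev <- eigen(I_W, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("The Louis information is not positive definite (smallest eigenvalue ",
         format(min(ev)), "); Monte Carlo error is too large - increase B.")
  }
  if (max(ev) / min(ev) > 1e12) {
    warning("Louis information is ill-conditioned (condition number ",
            format(max(ev) / min(ev), digits = 3), ").")
  }
  qrI <- qr(I_W)
  V <- qr.solve(qrI, diag(d))
  V <- (V + t(V)) / 2
  se <- sqrt(diag(V))
  nm <- colnames(I_W)
  if (!is.null(nm)) names(se) <- nm
  out <- list(covariance = V, se = se)
  if (!is.null(beta)) {
    z <- qnorm(1 - (1 - level) / 2)
    out$ci <- cbind(lower = beta - z * se, upper = beta + z * se)
    out$level <- level
  }
  out
}
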