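#' Importance weights for the Monte Carlo E-step
#'
#' For each observation `i` and imputation `b`, computes the importance
#' weight `q_i^(b)` proportional to
#' `f_Y(y_i | x_i^(b); beta) * f_X(x_i^(b))`, normalised over `b` separately
#' for each observation. Because the imputations are drawn from the
#' measurement-error distribution `f_U` itself, the proposal density cancels
#' the `f_W(w | x)` factor and only the response likelihood and covariate
#' prior appear. All arithmetic is on the log scale with per-row max
#' subtraction, so binomial/Poisson densities at moderate `n` do not
#' underflow.
#'
#' @param y Response vector (for capture-recapture fitters, the capture
#'   counts).
#' @param imps An [draw_imputations()] object.
#' @param fitter A fitter contract, e.g. [fitter_glm()].
#' @param prior A [prior_spec()] for the true covariates.
#' @param beta Coefficient vector at which the response likelihood is
#'   evaluated.
#' @param extra Optional fitter state (e.g. Gaussian dispersion) from the fit
#'   that produced `beta`.
#' @param base_weights Optional fixed per-observation likelihood weights
#'   (Berman-Turner quadrature weights enter here); default 1.
#' @param designs Optional precomputed list of per-replicate fitter designs
#'   (performance cache); built from `imps` when `NULL`.
#' @param data Raw covariate data frame used to rebuild designs when
#'   `designs` is `NULL`.
#' @return An `n x B` matrix of class `weight_matrix`; rows are non-negative
#'   and sum to one.
#' @export
compute_importance_weights <- function(y, imps, fitter, prior, beta,
                                       extra = NULL, base_weights = NULL,
                                       designs = NULL, data = NULL) {
  lt <- log_weight_terms(y, imps, fitter, prior, beta, extra, base_weights,
                         designs, data)
  normalise_log_weights(lt)
}

# Unnormalised log weight terms: bw_i * log f_Y + log f_X, an n x B matrix.
log_weight_terms <- function(y, imps, fitter, prior, beta, extra = NULL,
                             base_weights = NULL, designs = NULL, data = NULL) {
  B <- imps$B
  n <- imps$n
  bw <- base_weights %||% rep(1, n)
  if (is.null(designs)) {
    if (is.null(data)) stop("Supply either `designs` or `data`.")
    designs <- imputed_designs(fitter, data, imps)
  }
  lt <- matrix(NA_real_, n, B)
  for (b in seq_len(B)) {
    lfy <- fitter$log_density(y, designs[[b]], beta, extra)
    lfx <- prior_logdens(imps$values[[b]], prior)
    lt[, b] <- bw * lfy + lfx
  }
  lt
}

normalise_log_weights <- function(lt) {
  lse <- logsumexp_rows(lt)
  dead <- !is.finite(lse)
  if (any(dead)) {
    stop("All ", ncol(lt), " imputations underflowed for observation(s) ",
         paste(utils::head(which(dead), 5L), collapse = ", "),
         "; consider a larger B or check that sigma_u is plausible.")
  }
  q <- exp(lt - lse)
  q <- q / rowSums(q)  # tidy up residual rounding
  structure(q, class = c("weight_matrix", "matrix", "array"))
}

# Replace the contaminated columns of `data` by each imputation and return the
# fitter design for every replicate.
imputed_designs <- function(fitter, data, imps) {
  lapply(seq_len(imps$B), function(b) {
    d <- data
    d[imps$cols] <- as.data.frame(imps$values[[b]])
    fitter$design(d)
  })
}

# Stack the B imputed data sets into one nB-row data frame (replicate b owns
# rows ((b-1)n + 1) .. bn).
stack_imputed_data <- function(data, imps) {
  out <- data[rep(seq_len(imps$n), times = imps$B), , drop = FALSE]
  xs <- do.call(rbind, imps$values)
  out[imps$cols] <- as.data.frame(xs)
  rownames(out) <- NULL
  out
}

#' Effective sample size of the importance weights
#'
#' `ESS_i = 1 / sum_b (q_i^(b))^2` measures how many equally weighted draws
#' the weighted imputation sample for observation `i` is worth; it lies
#' between 1 (one imputation dominates) and `B` (uniform weights). Low mean
#' ESS signals that the prior proposal is a poor match to the posterior and
#' `B` should be increased.
#'
#' @param weights An `n x B` [compute_importance_weights()] matrix.
#' @return List with `per_obs` (length-`n` vector) and `mean`.
#' @export
effective_sample_size <- function(weights) {
  q <- unclass(weights)
  ess <- 1 / rowSums(q^2)
  list(per_obs = ess, mean = mean(ess))
}

#' Re-estimate the covariate prior from the weighted imputations
#'
#' The weighted mean and (maximum-likelihood, divide-by-`n`) weighted
#' covariance of the imputations under weights `q_i^(b) / n` are the exact
#' M-step maximisers of the normal prior parameters, so updating the prior
#' this way preserves the EM ascent property of the joint log-likelihood.
#'
#' @param imps An [draw_imputations()] object.
#' @param weights The current `n x B` weight matrix.
#' @param floor Eigenvalue floor passed to [prior_spec()].
#' @return A [prior_spec()].
#' @export
update_prior <- function(imps, weights, floor = 1e-6) {
  q <- unclass(weights) / imps$n
  p <- imps$p
  mu <- numeric(p)
  for (b in seq_len(imps$B)) {
    mu <- mu + colSums(imps$values[[b]] * q[, b])
  }
  S <- matrix(0, p, p)
  for (b in seq_len(imps$B)) {
    xc <- sweep(imps$values[[b]], 2, mu)
    S <- S + crossprod(xc * sqrt(q[, b]))
  }
  prior_spec(mu, S, floor = floor)
}

#' Monte Carlo observed-data log-likelihood
#'
#' Estimates the observed log-likelihood
#' `l(beta) = sum_i log{ (1/B) sum_b f_Y(y_i | x_i^(b); beta) f_X(x_i^(b)) }`,
#' i.e. the Q-function minus the entropy of the importance weights. Both
#' routes are computed and must agree to 1e-8 (they are algebraically
#' identical); the marginal form is returned.
#'
#' @inheritParams compute_importance_weights
#' @return Scalar log-likelihood estimate.
#' @export
observed_loglik <- function(y, imps, fitter, prior, beta, extra = NULL,
                            base_weights = NULL, designs = NULL, data = NULL) {
  lt <- log_weight_terms(y, imps, fitter, prior, beta, extra, base_weights,
                         designs, data)
  lse <- logsumexp_rows(lt)
  if (any(!is.finite(lse))) {
    stop("Log-likelihood underflow for observation(s) ",
         paste(utils::head(which(!is.finite(lse)), 5L), collapse = ", "))
  }
  ll_marginal <- sum(lse - log(imps$B))

  # identity check: Q - entropy = marginal (per observation)
  q <- exp(lt - lse)
  q <- q / rowSums(q)
  Qi <- rowSums(ifelse(q > 0, q * lt, 0))
  Hi <- rowSums(ifelse(q > 0, q * log(q), 0))
  ll_entropy <- sum(Qi - Hi) - imps$n * log(imps$B)
  if (abs(ll_entropy - ll_marginal) > 1e-8 * max(1, abs(ll_marginal))) {
    stop("Internal inconsistency: Q-minus-entropy and marginal log-likelihood ",
         "estimates disagree (", format(ll_entropy), " vs ",
         format(ll_marginal), ").")
  }
  ll_marginal
}
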