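#' Iteratively reweighted Monte Carlo EM for covariate measurement error
#'
#' The generic engine. Starting from a naive fit on the contaminated
#' covariates, it (1) draws `B` fixed imputations `x^(b) = w - u^(b)` of the
#' true covariates, (2) alternates an E-step that only updates importance
#' weights (no new imputations are ever drawn) with an M-step that refits the
#' wrapped weighted-likelihood estimator on the `nB`-row stacked data, and
#' (3) on convergence computes Louis-corrected standard errors, the Monte
#' Carlo observed log-likelihood, and effective-sample-size diagnostics.
#'
#' Convergence is declared when
#' `max|beta_new - beta_old| / max(1, max|beta_old|) < epsilon`.
#'
#' @param fitter A fitter contract ([fitter_glm()], [fitter_gam()],
#'   [fitter_posbinomial()], or [new_fitter()]).
#' @param y Response vector (capture counts for the positive-binomial
#'   fitter).
#' @param data Data frame of raw covariates (no response column); must
#'   contain the columns named in `spec$cols`.
#' @param spec An [me_spec()] describing the contaminated covariates.
#' @param B Number of Monte Carlo imputations (default 50).
#' @param epsilon Convergence threshold on the coefficient change
#'   (default 1e-5).
#' @param max_iter Maximum EM iterations (default 100); hitting it flags
#'   `converged = FALSE` with a warning.
#' @param seed Seed for the imputation draws; everything else is
#'   deterministic given it.
#' @param prior Optional [prior_spec()] for the true covariates; defaults to
#'   the moment-corrected prior `N(mean(w), cov(w) - sigma_u)`.
#' @param prior_update Re-estimate the prior each iteration from the weighted
#'   imputations (`TRUE`, default) or hold it fixed (`FALSE`).
#' @param base_weights Optional fixed per-observation likelihood weights
#'   (e.g. Berman-Turner quadrature weights); they multiply the importance
#'   weights in every refit.
#' @param conf_level Confidence level for Wald intervals.
#' @param verbose Print one trace line per iteration.
#' @return An object of class `mcem_fit`; see [tidy.mcem_fit()] and
#'   [glance.mcem_fit()] for tabular accessors. Key elements:
#'   `coefficients`, `se`, `covariance` (Louis), `ess` / `ess_mean`,
#'   `loglik` (observed-data, entropy-corrected), `trace` (per-iteration
#'   tibble), `converged`, `n_iter`, `prior`, `naive` (the initialising fit),
#'   `weights` (converged importance weights).
#' @export
run_mcem <- function(fitter, y, data, spec, B = 50, epsilon = 1e-5,
                     max_iter = 100, seed = 1L, prior = NULL,
                     prior_update = TRUE, base_weights = NULL,
                     conf_level = 0.95, verbose = FALSE) {
  stopifnot(inherits(fitter, "eiv_fitter"), inherits(spec, "me_spec"))
  data <- as.data.frame(data)
  miss <- setdiff(spec$cols, names(data))
  if (length(miss)) stop("Contaminated column(s) not in `data`: ",
                         paste(miss, collapse = ", "))
  n <- nrow(data)
  if (length(y) != n) stop("`y` and `data` disagree on n.")
  bw <- base_weights %||% rep(1, n)

  w <- as.matrix(data[spec$cols])

  # Step 1a: naive fit, G(y; w; 1)
  D0 <- fitter$design(data)
  naive <- fitter$fit(y, D0, bw)
  beta <- naive$beta
  d <- length(beta)

  # Step 1b-1c: fixed imputations, stacked replicate data
  imps <- draw_imputations(w, spec, B, seed)
  designs <- imputed_designs(fitter, data, imps)
  data_stack <- stack_imputed_data(data, imps)
  D_stack <- fitter$design(data_stack)
  y_stack <- rep(y, times = B)
  bw_stack <- rep(bw, times = B)

  if (is.null(prior)) prior <- moment_prior(w, spec)

  extra <- naive$extra
  trace <- vector("list", max_iter)
  converged <- FALSE
  iter <- 0L
  fit <- naive
  repeat {
    iter <- iter + 1L
    # E-step: update weights only
    q <- compute_importance_weights(y, imps, fitter, prior, beta,
                                    extra = extra, base_weights = bw,
                                    designs = designs)
    if (prior_update) prior <- update_prior(imps, q)

    # M-step: weighted refit on the stacked replicates
    q_stack <- as.vector(unclass(q)) * bw_stack
    fit <- tryCatch(
      fitter$fit(y_stack, D_stack, q_stack),
      error = function(e) stop("M-step fitter failed at EM iteration ", iter,
                               ": ", conditionMessage(e), call. = FALSE)
    )
    beta_new <- fit$beta
    extra <- fit$extra

    ll <- observed_loglik(y, imps, fitter, prior, beta_new, extra = extra,
                          base_weights = bw, designs = designs)
    if (!is.finite(ll)) {
      stop("Non-finite observed log-likelihood at EM iteration ", iter,
           "; trace so far:\n",
           paste(vapply(trace[seq_len(iter - 1L)], function(tr)
             paste(tr$iter, format(tr$loglik), format(tr$delta)),
             character(1)), collapse = "\n"))
    }
    delta <- max(abs(beta_new - beta)) / max(1, max(abs(beta)))
    trace[[iter]] <- list(iter = iter, loglik = ll, delta = delta)
    if (verbose) message(sprintf("iter %3d  loglik %.6f  max|dbeta| %.3e",
                                 iter, ll, delta))
    beta <- beta_new
    if (delta < epsilon) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) {
    warning("MCEM did not converge in ", max_iter,
            " iterations (last relative change ",
            format(trace[[iter]]$delta, digits = 3), ").")
  }

  # final E-step at the converged coefficients, for diagnostics and SEs
  q <- compute_importance_weights(y, imps, fitter, prior, beta,
                                  extra = extra, base_weights = bw,
                                  designs = designs)
  ess <- effective_sample_size(q)
  scoreset <- per_obs_score_jacobian(fitter, y, imps, beta, extra = extra,
                                     base_weights = bw, designs = designs)
  pen <- if (!is.null(fitter$penalty_hessian)) fitter$penalty_hessian(extra) else NULL
  IW <- louis_information(scoreset, q, penalty = pen)
  vc <- coefficient_covariance(IW, beta = beta, level = conf_level)

  trace_tbl <- dplyr::bind_rows(lapply(trace[seq_len(iter)], tibble::as_tibble))

  structure(list(
    coefficients = beta,
    se = vc$se,
    covariance = vc$covariance,
    ci = vc$ci,
    conf_level = conf_level,
    information = IW,
    ess = ess$per_obs,
    ess_mean = ess$mean,
    loglik = trace[[iter]]$loglik,
    edf = fit$edf,
    trace = trace_tbl,
    converged = converged,
    n_iter = iter,
    prior = prior,
    weights = q,
    imputations = imps,
    naive = naive,
    fitter = fitter,
    spec = spec,
    B = B,
    epsilon = epsilon,
    seed = seed,
    y = y,
    data = data,
    base_weights = base_weights,
    extra = extra,
    nobs = n
  ), class = "mcem_fit")
}

#' One weighted-refit M-step
#'
#' Regresses the `B` response replicates against the imputed covariates with
#' the current importance weights: the stacked `nB`-row data set
#' `{(y, x^(1)), ..., (y, x^(B))}` is handed to the wrapped fitter with
#' observation weights `q_i^(b)` (times any base weights). Exposed mainly
#' for testing and for building custom EM loops; [run_mcem()] does this
#' internally.
#'
#' @inheritParams run_mcem
#' @param imps A [draw_imputations()] object.
#' @param weights The current `n x B` importance-weight matrix.
#' @return The fitter's fit result on the stacked data (`beta`, `loglik`,
#'   `edf`, ...).
#' @export
m_step <- function(fitter, y, data, imps, weights, base_weights = NULL) {
  n <- imps$n
  bw <- base_weights %||% rep(1, n)
  data_stack <- stack_imputed_data(as.data.frame(data), imps)
  D_stack <- fitter$design(data_stack)
  q_stack <- as.vector(unclass(weights)) * rep(bw, times = imps$B)
  fitter$fit(rep(y, times = imps$B), D_stack, q_stack)
}

#' Refit a regression model accounting for covariate measurement error
#'
#' Data-frame-first front end to [run_mcem()] for GLMs and GAMs: give it the
#' data, a model formula, the response family, the names of the
#' error-contaminated covariates and their known error variance, and it
#' returns a measurement-error-corrected fit with Louis standard errors.
#' Formulas containing `s(...)` terms are fitted as penalised-spline GAMs via
#' mgcv; all other formulas as GLMs.
#'
#' @param data Data frame holding the response and covariates.
#' @param formula Two-sided model formula, e.g.
#'   `chd ~ sbp + chol + age + smoke` or `y ~ s(x) + s(z)`. Polynomial terms
#'   in a contaminated covariate (e.g. `I(w^2)`) are rebuilt from each
#'   imputation.
#' @param family `"gaussian"`, `"binomial"` or `"poisson"`.
#' @param error_cols Names of the contaminated covariates.
#' @param sigma_u Known error variance(s): scalar, vector or matrix (see
#'   [me_spec()]).
#' @inheritParams run_mcem
#' @param ... Passed on to [run_mcem()] (e.g. `prior`, `prior_update`,
#'   `verbose`).
#' @return An `mcem_fit` object.
#' @examples
#' set.seed(1)
#' n <- 400
#' x <- rnorm(n)
#' w <- x + rnorm(n, sd = sqrt(0.25))
#' y <- rbinom(n, 1, plogis(0.5 + x - 0.3 * x^2))
#' d <- data.frame(y = y, w = w)
#' fit <- mcem_refit(d, y ~ w + I(w^2), family = "binomial",
#'                   error_cols = "w", sigma_u = 0.25, B = 20, seed = 1)
#' tidy(fit)
#' @export
mcem_refit <- function(data, formula, family = "binomial", error_cols,
                       sigma_u, B = 50, epsilon = 1e-5, max_iter = 100,
                       seed = 1L, conf_level = 0.95, ...) {
  data <- as.data.frame(data)
  resp <- all.vars(formula[[2]])
  if (length(resp) != 1L || !resp %in% names(data)) {
    stop("The formula response must be a single column of `data`.")
  }
  y <- data[[resp]]
  covdata <- data[setdiff(names(data), resp)]
  spec <- me_spec(error_cols, sigma_u)
  rhs <- formula
  rhs[[2]] <- NULL  # drop response -> one-sided

  has_smooth <- any(grepl("(^|[^[:alnum:]._])s\\(",
                          attr(terms(formula, data = data), "term.labels")))
  fitter <- if (has_smooth) {
    fitter_gam(rhs, covdata, family = family)
  } else {
    fitter_glm(rhs, covdata, family = family)
  }
  out <- run_mcem(fitter, y, covdata, spec, B = B, epsilon = epsilon,
                  max_iter = max_iter, seed = seed, conf_level = conf_level,
                  ...)
  out$formula <- formula
  out$response <- resp
  out$family <- family
  out
}

#' @export
print.mcem_fit <- function(x, ...) {
  cat("Measurement-error-corrected fit (Monte Carlo EM)\n")
  if (!is.null(x$formula)) cat("  model: ", deparse(x$formula), "\n", sep = "")
  cat("  fitter: ", x$fitter$label, "\n", sep = "")
  cat("  contaminated: ", paste(x$spec$cols, collapse = ", "),
      "  (B = ", x$B, ")\n", sep = "")
  cat(if (x$converged) "  converged" else "  NOT converged", "after",
      x$n_iter, "EM iterations\n")
  cat("  observed log-likelihood:", format(x$loglik, digits = 7),
      "  mean ESS:", format(x$ess_mean, digits = 4), "\n\n")
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$se)
  print(round(tab, 4))
  invisible(x)
}

#' Linear predictor / fitted values for an MCEM fit
#'
#' @param object An `mcem_fit`.
#' @param newdata Data frame of covariates; defaults to the training
#'   covariates.
#' @param type `"link"` (linear predictor) or `"response"`.
#' @param ... Unused.
#' @export
predict.mcem_fit <- function(object, newdata = NULL,
                             type = c("link", "response"), ...) {
  type <- match.arg(type)
  newdata <- if (is.null(newdata)) object$data else as.data.frame(newdata)
  D <- object$fitter$design(newdata)
  eta <- object$fitter$predict(D, object$coefficients, object$extra)
  if (type == "link") return(eta)
  fam <- object$family %||% object$extra$family %||% "gaussian"
  glm_mu(eta, fam)
}
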