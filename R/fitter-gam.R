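#' Weighted penalised-spline GAM fit
#'
#' Maximises the weighted log-likelihood minus the smoothing penalty
#' `(1/2) sum_j lambda_j beta' S_j beta` via [mgcv::gam()]. By default the
#' smoothing parameters are re-selected (GCV/Mallows' Cp) on every weighted
#' refit; supply `sp` to freeze them.
#'
#' @param y Response vector.
#' @param data Covariate data frame.
#' @param q Non-negative observation weights.
#' @param formula One-sided formula with at least one `s()` term, e.g.
#'   `~ s(x) + s(z)`.
#' @param family `"gaussian"`, `"binomial"` or `"poisson"`.
#' @param sp Optional fixed smoothing-parameter vector.
#' @return List with `beta`, `linear_predictor`, `loglik`, `edf`,
#'   `converged`, `extra` (carries the mgcv fit).
#' @export
fit_weighted_gam <- function(y, data, q, formula, family = "poisson",
                             sp = NULL) {
  fam <- glm_family(family)
  df <- as.data.frame(data)
  df$.eiv_y <- y
  df$.eiv_q <- as.numeric(q)
  full <- stats::update.formula(formula, .eiv_y ~ .)
  g <- suppressWarnings(
    mgcv::gam(full, family = fam, data = df, weights = .eiv_q,
              sp = sp, method = "GCV.Cp")
  )
  if (!g$converged) stop("mgcv smoothing-parameter iteration did not converge.")
  beta <- coef(g)
  phi <- if (fam$family == "gaussian") {
    sum(df$.eiv_q * (y - g$fitted.values)^2) / sum(df$.eiv_q)
  } else 1
  eta <- g$linear.predictors
  list(beta = beta,
       linear_predictor = eta,
       loglik = sum(df$.eiv_q * glm_logdens(y, eta, fam$family, phi)),
       edf = sum(g$edf),
       converged = TRUE,
       extra = list(gam = g, dispersion = phi, family = fam$family,
                    sp = g$sp))
}

# Assemble the penalty curvature sum_j lambda_j S_j / phi on the
# log-likelihood scale (mgcv penalises the deviance, i.e. 2*phi*loglik).
gam_penalty_hessian <- function(extra) {
  g <- extra$gam
  d <- length(coef(g))
  S <- matrix(0, d, d)
  sp <- g$full.sp %||% g$sp
  k <- 0L
  for (sm in g$smooth) {
    idx <- sm$first.para:sm$last.para
    for (j in seq_along(sm$S)) {
      k <- k + 1L
      S[idx, idx] <- S[idx, idx] + sp[k] * sm$S[[j]]
    }
  }
  S / extra$dispersion
}

#' GAM fitter contract for the EM engine
#'
#' Wraps [fit_weighted_gam()] as a fitter contract for [run_mcem()]. The
#' "design" handed around is the raw covariate data frame; smooth bases are
#' evaluated through the current mgcv fit's prediction matrix, so imputed
#' covariate values pass through the same basis as the fit itself. Within an
#' EM run the stacked imputed data are fixed, so the basis and knots are
#' identical across iterations and coefficients are comparable.
#'
#' @param formula One-sided smooth formula, e.g. `~ s(w) + s(z)`.
#' @param data Template covariate data frame.
#' @param family `"gaussian"`, `"binomial"` or `"poisson"`.
#' @param sp `NULL` to re-select smoothing parameters by GCV at every M-step
#'   (default), or a fixed vector to freeze them (e.g. at the naive fit's
#'   values).
#' @return An [new_fitter()] object.
#' @export
fitter_gam <- function(formula, data, family = "poisson", sp = NULL) {
  fam <- glm_family(family)$family

  lp <- function(D, extra) {
    mgcv::predict.gam(extra$gam, newdata = as.data.frame(D),
                      type = "lpmatrix")
  }
  new_fitter(
    design = function(data) as.data.frame(data),
    fit = function(y, D, q) fit_weighted_gam(y, D, q, formula, fam, sp = sp),
    log_density = function(y, D, beta, extra) {
      eta <- drop(lp(D, extra) %*% beta)
      glm_logdens(y, eta, fam, extra$dispersion %||% 1)
    },
    score = function(y, D, beta, extra) {
      Xp <- lp(D, extra)
      mu <- glm_mu(drop(Xp %*% beta), fam)
      Xp * ((y - mu) / (extra$dispersion %||% 1))
    },
    jacobian = function(y, D, beta, extra) {
      Xp <- lp(D, extra)
      mu <- glm_mu(drop(Xp %*% beta), fam)
      v <- glm_dmu(mu, fam) / (extra$dispersion %||% 1)
      d <- ncol(Xp)
      arr <- array(0, c(d, d, nrow(Xp)))
      for (j in seq_len(d)) {
        for (k in seq_len(j)) {
          val <- -v * Xp[, j] * Xp[, k]
          arr[j, k, ] <- val
          arr[k, j, ] <- val
        }
      }
      arr
    },
    predict = function(D, beta, extra) drop(lp(D, extra) %*% beta),
    penalty_hessian = gam_penalty_hessian,
    label = paste0("weighted penalised-spline GAM (", fam, ", mgcv)")
  )
}
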