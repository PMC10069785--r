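#' Full B-spline basis with the partition-of-unity property
#'
#' Evaluates the complete B-spline basis (including the functions that span
#' the constant), with interior knots at sample quantiles. Rows sum to one at
#' any point inside the boundary knots; points outside are clamped to the
#' boundary. Because the full basis spans the intercept, a design built from
#' it needs no separate constant column.
#'
#' @param x Points at which to evaluate.
#' @param df Number of basis functions (`>= degree + 1`).
#' @param degree Spline degree (default 3, cubic).
#' @param knots Optional full knot vector (overrides `df`); as produced by a
#'   previous call's `"knots"` attribute, for evaluating the same basis at
#'   new points.
#' @param boundary Boundary knots; default `range(x)`.
#' @return `length(x) x df` matrix with a `"knots"` attribute.
#' @export
bspline_basis <- function(x, df = 8, degree = 3, knots = NULL,
                          boundary = range(x)) {
  if (is.null(knots)) {
    n_int <- df - degree - 1
    if (n_int < 0) stop("`df` must be at least degree + 1.")
    interior <- if (n_int > 0) {
      stats::quantile(x, probs = seq_len(n_int) / (n_int + 1), names = FALSE)
    } else numeric(0)
    knots <- c(rep(boundary[1], degree + 1), interior,
               rep(boundary[2], degree + 1))
  }
  lo <- knots[1]; hi <- knots[length(knots)]
  xc <- pmin(pmax(x, lo), hi)
  Bmat <- splines::splineDesign(knots, xc, ord = degree + 1)
  attr(Bmat, "knots") <- knots
  Bmat
}

# conditional log-likelihood pieces for the zero-truncated (positive)
# binomial: l_i = c log p + (tau - c) log(1 - p) - log{1 - (1 - p)^tau}
posbinom_logdens <- function(cvec, eta, tau) {
  p <- plogis(eta)
  A <- (1 - p)^tau
  cvec * log(p) + (tau - cvec) * log1p(-p) - log1p(-A)
}

# score in eta: c - tau * p / (1 - (1 - p)^tau)  (c minus conditional mean)
posbinom_score_eta <- function(cvec, eta, tau) {
  p <- plogis(eta)
  cvec - tau * p / (1 - (1 - p)^tau)
}

# second derivative in eta (analytic)
posbinom_jac_eta <- function(eta, tau) {
  p <- plogis(eta)
  A <- (1 - p)^tau
  denom <- 1 - A
  -tau * p * (1 - p) / denom + tau^2 * p^2 * A / denom^2
}

#' Weighted positive-binomial conditional-likelihood fit
#'
#' Capture-recapture conditional likelihood for a closed population:
#' conditional on being captured at least once in `tau` occasions, an
#' individual with occasion-constant capture probability
#' `p_i = logistic(eta_i)` contributes
#' `p^c (1-p)^(tau-c) / {1 - (1-p)^tau}` where `c` is its capture count.
#' Maximised by Newton's method with analytic gradient and Hessian and
#' step-halving; observation weights `q_i` exponentiate the contributions.
#'
#' @param histories `n x tau` 0/1 capture-history matrix (every row must
#'   contain at least one capture), or a vector of capture counts.
#' @param X Design matrix for the linear predictor (include the intercept
#'   column, or use a full B-spline basis which spans it).
#' @param q Non-negative observation weights.
#' @param tau Number of capture occasions (required when `histories` is a
#'   count vector).
#' @return List with `beta`, `linear_predictor`, `p` (capture
#'   probabilities), `loglik`, `edf`, `converged`, `extra`.
#' @export
fit_weighted_posbinomial <- function(histories, X, q = NULL, tau = NULL) {
  if (is.matrix(histories) || is.data.frame(histories)) {
    H <- as.matrix(histories)
    if (!all(H %in% c(0, 1))) stop("Capture histories must be 0/1.")
    cvec <- rowSums(H)
    tau <- ncol(H)
  } else {
    cvec <- as.numeric(histories)
    if (is.null(tau)) stop("Supply `tau` when giving capture counts.")
  }
  if (any(cvec < 1)) {
    stop("Individual(s) ", paste(utils::head(which(cvec < 1), 5), collapse = ", "),
         " have all-zero capture histories; the conditional likelihood is ",
         "defined only for captured individuals.")
  }
  X <- as.matrix(X)
  n <- length(cvec)
  q <- q %||% rep(1, n)

  # moment start: intercept at the count-matching probability, slopes 0
  pbar <- min(max(sum(q * cvec) / (sum(q) * tau), 1e-3), 1 - 1e-3)
  beta <- qr.solve(crossprod(X), crossprod(X, rep(qlogis(pbar), n)))
  beta <- drop(beta)

  ll <- function(b) sum(q * posbinom_logdens(cvec, drop(X %*% b), tau))
  ll_old <- ll(beta)
  converged <- FALSE
  for (it in 1:200) {
    eta <- drop(X %*% beta)
    g <- crossprod(X, q * posbinom_score_eta(cvec, eta, tau))
    Hm <- crossprod(X, X * (q * posbinom_jac_eta(eta, tau)))
    step <- tryCatch(qr.solve(Hm, g), error = function(e)
      stop("Singular Hessian in positive-binomial fit: ", conditionMessage(e)))
    halve <- 1
    repeat {
      beta_new <- beta - halve * drop(step)
      ll_new <- ll(beta_new)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
      halve <- halve / 2
      if (halve < 1e-8) { beta_new <- beta; ll_new <- ll_old; break }
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    ll_old <- ll_new
    if (delta < 1e-10) { converged <- TRUE; break }
  }
  if (!converged) stop("Positive-binomial Newton iteration did not converge.")
  eta <- drop(X %*% beta)
  list(beta = setNames(beta, colnames(X)),
       linear_predictor = eta,
       p = plogis(eta),
       loglik = ll_old,
       edf = ncol(X),
       converged = TRUE,
       extra = list(tau = tau))
}

#' Positive-binomial fitter contract for the EM engine
#'
#' Capture-probability model `p_i = logistic(eta_i)` with `eta_i` linear or a
#' B-spline smooth in one individual covariate, fitted by the weighted
#' conditional likelihood. The response handed to [run_mcem()] is the vector
#' of capture counts. Spline knots are computed once from the template
#' (observed) covariate values and frozen, with boundary knots widened so
#' imputed values stay inside.
#'
#' @param tau Number of capture occasions.
#' @param covariate Name of the individual covariate column.
#' @param data Template covariate data frame (knot placement).
#' @param spline_df `NULL` for a linear predictor; otherwise the B-spline
#'   basis dimension.
#' @param boundary_pad Widening of the spline boundary knots, in covariate
#'   units (default 4 standard deviations of the template covariate).
#' @return An [new_fitter()] object.
#' @export
fitter_posbinomial <- function(tau, covariate, data, spline_df = NULL,
                               boundary_pad = NULL) {
  x0 <- data[[covariate]]
  if (is.null(x0)) stop("Column '", covariate, "' not found in `data`.")
  knots <- NULL
  if (!is.null(spline_df)) {
    pad <- boundary_pad %||% (4 * sd(x0))
    knots <- attr(bspline_basis(x0, df = spline_df,
                                boundary = range(x0) + c(-pad, pad)),
                  "knots")
  }
  design <- function(data) {
    x <- data[[covariate]]
    if (is.null(spline_df)) {
      cbind("(Intercept)" = 1, x = x)
    } else {
      Bm <- bspline_basis(x, knots = knots)
      colnames(Bm) <- paste0("bs", seq_len(ncol(Bm)))
      Bm
    }
  }
  new_fitter(
    design = design,
    fit = function(y, D, q) fit_weighted_posbinomial(y, D, q, tau = tau),
    log_density = function(y, D, beta, extra) {
      posbinom_logdens(y, drop(D %*% beta), tau)
    },
    score = function(y, D, beta, extra) {
      D * posbinom_score_eta(y, drop(D %*% beta), tau)
    },
    jacobian = function(y, D, beta, extra) {
      jj <- posbinom_jac_eta(drop(D %*% beta), tau)
      d <- ncol(D)
      arr <- array(0, c(d, d, nrow(D)))
      for (j in seq_len(d)) {
        for (k in seq_len(j)) {
          val <- jj * D[, j] * D[, k]
          arr[j, k, ] <- val
          arr[k, j, ] <- val
        }
      }
      arr
    },
    predict = function(D, beta, extra = NULL) drop(D %*% beta),
    label = paste0("weighted positive-binomial conditional likelihood (tau = ",
                   tau, ")")
  )
}
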