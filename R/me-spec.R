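#' Declare which covariates carry classical measurement error
#'
#' Specifies the error-contaminated covariates and their known error
#' covariance under the classical additive model `W = X + U`, with
#' `U ~ N(0, sigma_u)` independent of the true covariate `X`. The error
#' variance is assumed known (estimated externally, e.g. from replicate
#' measurements or validation data).
#'
#' @param cols Character vector naming the contaminated covariate columns
#'   (order defines the rows/columns of `sigma_u`).
#' @param sigma_u Known measurement-error variance: a scalar (one contaminated
#'   covariate, or a common variance), a vector of per-covariate variances, or
#'   a full `p x p` covariance matrix. Units are squared covariate units.
#' @return An object of class `me_spec` with elements `cols` and `sigma_u`
#'   (always stored as a `p x p` matrix).
#' @examples
#' me_spec("sbp", 0.006295)
#' me_spec(c("temp", "rain"), c(0.25, 0.1))
#' @export
me_spec <- function(cols, sigma_u) {
  if (!is.character(cols) || length(cols) < 1L) {
    stop("`cols` must be a non-empty character vector of covariate names.")
  }
  if (anyDuplicated(cols)) stop("`cols` must not contain duplicates.")
  p <- length(cols)
  S <- sigma_u
  if (is.null(dim(S))) {
    if (length(S) == 1L) S <- diag(rep(as.numeric(S), p), nrow = p)
    else if (length(S) == p) S <- diag(as.numeric(S), nrow = p)
    else stop("`sigma_u` vector must have length 1 or length(cols).")
  } else {
    S <- as.matrix(S)
    if (!all(dim(S) == p)) {
      stop("`sigma_u` matrix must be ", p, " x ", p, " to match `cols`.")
    }
  }
  if (any(!is.finite(S))) stop("`sigma_u` must be finite.")
  if (max(abs(S - t(S))) > 1e-10) {
    stop("`sigma_u` must be symmetric; the supplied matrix is not.")
  }
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) {
    stop("`sigma_u` is not positive semi-definite (smallest eigenvalue ",
         format(min(ev)), "); check the supplied error covariance.")
  }
  dimnames(S) <- list(cols, cols)
  structure(list(cols = cols, sigma_u = S), class = "me_spec")
}

#' @export
print.me_spec <- function(x, ...) {
  cat("Classical measurement-error specification\n")
  cat("  contaminated covariates:", paste(x$cols, collapse = ", "), "\n")
  cat("  error covariance Sigma_u:\n")
  print(x$sigma_u)
  invisible(x)
}

#' Multivariate normal prior for the true covariates
#'
#' The structural model assumes the error-free covariates `X` follow a
#' multivariate normal distribution `f_X`. The covariance is floored in its
#' eigenvalues so the prior density is always proper.
#'
#' @param mean Numeric `p`-vector of prior means.
#' @param cov `p x p` symmetric covariance matrix (a scalar for `p = 1`).
#' @param floor Eigenvalue floor, as a fraction of the trace.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(mean, cov, floor = 1e-6) {
  mean <- as.numeric(mean)
  p <- length(mean)
  if (is.null(dim(cov))) {
    if (length(cov) == 1L && p == 1L) cov <- matrix(cov, 1, 1)
    else if (length(cov) == p) cov <- diag(as.numeric(cov), nrow = p)
    else stop("`cov` must be a ", p, " x ", p, " matrix.")
  }
  cov <- as.matrix(cov)
  if (!all(dim(cov) == p)) stop("`cov` must be ", p, " x ", p, ".")
  if (max(abs(cov - t(cov))) > 1e-8) stop("`cov` must be symmetric.")
  cov <- floor_cov((cov + t(cov)) / 2, floor)
  structure(list(mean = mean, cov = cov), class = "prior_spec")
}

# Floor the eigenvalues of a symmetric matrix at `floor * trace` (with an
# absolute fallback when the trace is ~0), so downstream densities are proper.
floor_cov <- function(S, floor = 1e-6) {
  e <- eigen(S, symmetric = TRUE)
  tr <- sum(diag(S))
  lo <- max(floor * tr, 1e-12)
  vals <- pmax(e$values, lo)
  if (all(vals <= 0)) stop("Degenerate prior covariance: trace is not positive.")
  out <- e$vectors %*% (vals * t(e$vectors))
  (out + t(out)) / 2
}

# Log-density of rows of x under a prior_spec (n x p matrix in, n-vector out).
prior_logdens <- function(x, prior) {
  x <- as.matrix(x)
  p <- length(prior$mean)
  if (p == 1L) {
    dnorm(drop(x), mean = prior$mean, sd = sqrt(prior$cov[1, 1]), log = TRUE)
  } else {
    mvtnorm::dmvnorm(x, mean = prior$mean, sigma = prior$cov, log = TRUE)
  }
}

# Moment-corrected starting prior: mean(w), cov(w) - Sigma_u, floored.
moment_prior <- function(w, spec, floor = 1e-6) {
  w <- as.matrix(w)
  n <- nrow(w)
  mu <- colMeans(w)
  Sw <- crossprod(sweep(w, 2, mu)) / n
  prior_spec(mu, Sw - spec$sigma_u, floor = floor)
}
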