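#' Draw the fixed Monte Carlo imputations of the true covariates
#'
#' Simulates `B` replicate measurement-error draws `u^(b) ~ N(0, Sigma_u)` and
#' constructs imputed true covariates `x^(b) = w - u^(b)`. The draws are made
#' once and held fixed for the whole EM run: conditional on them the
#' iteratively reweighted procedure is an exact EM algorithm, and only the
#' importance weights change between iterations.
#'
#' @param w `n x p` matrix (or data frame) of observed contaminated covariate
#'   values, columns ordered as `spec$cols`.
#' @param spec An [me_spec()] object.
#' @param B Number of Monte Carlo replicates (`>= 1`).
#' @param seed Integer seed; the same seed reproduces the draws exactly.
#' @return An object of class `imputation_set`: a list with `values` (length-`B`
#'   list of `n x p` imputed matrices), `draws` (the `u^(b)`), `B`, `n`, `p`,
#'   and `seed`.
#' @export
draw_imputations <- function(w, spec, B, seed = 1L) {
  stopifnot(inherits(spec, "me_spec"))
  w <- as.matrix(w)
  if (any(!is.finite(w))) stop("`w` must be finite.")
  p <- length(spec$cols)
  if (ncol(w) != p) stop("`w` must have ", p, " columns (one per contaminated covariate).")
  B <- as.integer(B)
  if (B < 1L) stop("`B` must be at least 1.")
  n <- nrow(w)

  # symmetric square root of Sigma_u; handles the PSD-but-singular case
  # (including Sigma_u = 0, where every imputation equals w exactly)
  e <- eigen(spec$sigma_u, symmetric = TRUE)
  root <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  draws <- vector("list", B)
  values <- vector("list", B)
  for (b in seq_len(B)) {
    u <- matrix(rnorm(n * p), n, p) %*% root
    colnames(u) <- spec$cols
    draws[[b]] <- u
    values[[b]] <- w - u
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  structure(list(values = values, draws = draws, B = B, n = n, p = p,
                 seed = as.integer(seed), cols = spec$cols),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("Monte Carlo imputation set: B =", x$B, "replicates of", x$n, "x", x$p,
      "covariates (seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}
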