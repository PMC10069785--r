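#' Simulation-study design
#'
#' Describes one of the benchmark simulation designs: a quadratic logistic
#' GLM `logit P(Y=1) = b0 + b1 X + b2 X^2` with true coefficients
#' `(0.5, 1, -0.3)` at `n = 800`, or a smooth Poisson model with
#' `log E(Y) = cos(2X + 1/4)`; the true covariate is standard normal by
#' default, with chi-squared and skew-normal alternatives for robustness
#' experiments; classical error `U ~ N(0, sigma_u2)` contaminates it.
#'
#' @param n Training sample size.
#' @param n_star Test sample size (prediction experiments).
#' @param beta_true Coefficients of the logistic-quadratic response.
#' @param sigma_u2 Grid of measurement-error variances.
#' @param x_distribution `"normal"`, `"scaled_chisq3"` (`(chi^2_3 - 3)/6`),
#'   or `"skew_normal"` (two-piece, skewness `kappa`).
#' @param response `"logistic_quadratic"` or `"poisson_smooth"`.
#' @param n_datasets Number of replicate data sets.
#' @param seed Base seed; each replicate derives its own seed from it.
#' @param kappa Skew-normal skewness parameter.
#' @param standardize Rescale the chi-squared covariate to unit variance
#'   (divide by `sqrt(6)` instead of the literal 6).
#' @return A `sim_design` list.
#' @export
sim_design <- function(n = 800, n_star = 200, beta_true = c(0.5, 1, -0.3),
                       sigma_u2 = c(0.25, 0.5, 0.75),
                       x_distribution = c("normal", "scaled_chisq3",
                                          "skew_normal"),
                       response = c("logistic_quadratic", "poisson_smooth"),
                       n_datasets = 200, seed = 1L, kappa = 3,
                       standardize = FALSE) {
  x_distribution <- match.arg(x_distribution)
  response <- match.arg(response)
  stopifnot(n_datasets >= 1, all(sigma_u2 >= 0))
  structure(list(n = n, n_star = n_star, beta_true = beta_true,
                 sigma_u2 = sigma_u2, x_distribution = x_distribution,
                 response = response, n_datasets = n_datasets,
                 seed = as.integer(seed), kappa = kappa,
                 standardize = standardize),
            class = "sim_design")
}

#' Draw a true-covariate sample
#'
#' @param n Sample size.
#' @param distribution `"normal"` (standard normal), `"scaled_chisq3"`
#'   (`(chi^2_3 - 3)/6`, or divided by `sqrt(6)` when `standardize`), or
#'   `"skew_normal"`: the two-piece density
#'   `f(x|k) = 2/(k + 1/k) {phi(x/k) 1[x>=0] + phi(xk) 1[x<0]}`, sampled by
#'   returning `k|Z|` with probability `k^2/(k^2+1)` and `-|Z|/k` otherwise.
#' @param seed Optional seed.
#' @param kappa Skewness parameter for the skew normal.
#' @param standardize See above.
#' @return Numeric vector of length `n`.
#' @export
gen_covariate <- function(n, distribution = "normal", seed = NULL, kappa = 3,
                          standardize = FALSE) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  switch(distribution,
         normal = rnorm(n),
         scaled_chisq3 = (rchisq(n, df = 3) - 3) /
           if (standardize) sqrt(6) else 6,
         skew_normal = {
           z <- abs(rnorm(n))
           pos <- runif(n) < kappa^2 / (kappa^2 + 1)
           ifelse(pos, kappa * z, -z / kappa)
         },
         stop("Unknown covariate distribution '", distribution, "'."))
}

# deterministic per-replicate seed below 2^31
replicate_seed <- function(seed, rep_index, salt = 0L) {
  as.integer((as.double(seed) * 1000003 + rep_index * 7919 + salt) %% 2147483629)
}

true_eta <- function(x, design) {
  if (design$response == "logistic_quadratic") {
    b <- design$beta_true
    b[1] + b[2] * x + b[3] * x^2
  } else {
    cos(2 * x + 1 / 4)
  }
}

#' Generate one replicate data set
#'
#' Draws the true covariate, the response from the design's model, and the
#' contaminated covariate `w = x + u`, `u ~ N(0, sigma_u2)`. Deterministic
#' given `(design$seed, rep_index, sigma_u2)`.
#'
#' @param design A [sim_design()].
#' @param rep_index Replicate number (1-based).
#' @param sigma_u2 Measurement-error variance for this replicate (defaults
#'   to the first entry of the design grid).
#' @param n Sample size override (e.g. for test sets).
#' @param salt Extra seed offset (used to make test sets independent).
#' @return Tibble with columns `y`, `x` (true), `w` (observed); the design
#'   is attached as attribute `"design"`.
#' @export
gen_dataset <- function(design, rep_index = 1L, sigma_u2 = NULL, n = NULL,
                        salt = 0L) {
  stopifnot(inherits(design, "sim_design"))
  sigma_u2 <- sigma_u2 %||% design$sigma_u2[1]
  n <- n %||% design$n
  set.seed(replicate_seed(design$seed, rep_index, salt))
  x <- gen_covariate(n, design$x_distribution, kappa = design$kappa,
                     standardize = design$standardize)
  eta <- true_eta(x, design)
  y <- if (design$response == "logistic_quadratic") {
    rbinom(n, 1, plogis(eta))
  } else {
    rpois(n, exp(eta))
  }
  u <- if (sigma_u2 > 0) rnorm(n, sd = sqrt(sigma_u2)) else rep(0, n)
  out <- tibble::tibble(y = y, x = x, w = x + u)
  attr(out, "design") <- design
  attr(out, "sigma_u2") <- sigma_u2
  out
}

#' Run a bias / RMSE / coverage simulation study
#'
#' For each error variance in the design grid and each replicate, fits the
#' naive model (contaminated covariate treated as error-free) and the
#' EM-corrected model, and summarises the quadratic coefficient
#' (`beta_X`, truth `-0.3` under the default design): relative bias
#' `mean(est - truth)/|truth|`, RMSE, and empirical coverage of the Wald
#' interval at `conf_level`. Replicate-level failures are dropped with a
#' count reported.
#'
#' @param design A [sim_design()] with `response = "logistic_quadratic"`.
#' @param methods Subset of `c("naive", "mcem")`.
#' @param B Monte Carlo size for the EM runs.
#' @param conf_level Wald interval level.
#' @param epsilon,max_iter EM controls.
#' @return Summary tibble (method x sigma_u2 with `rel_bias`, `rmse`,
#'   `coverage`, `n_ok`, `n_fail`); the per-replicate results are attached
#'   as attribute `"replicates"`.
#' @export
run_sim_study <- function(design, methods = c("naive", "mcem"), B = 50,
                          conf_level = 0.95, epsilon = 1e-5, max_iter = 100) {
  stopifnot(inherits(design, "sim_design"),
            design$response == "logistic_quadratic",
            design$n_datasets >= 2)
  truth <- design$beta_true[3]
  z <- qnorm(1 - (1 - conf_level) / 2)
  rows <- list()
  for (s2 in design$sigma_u2) {
    for (r in seq_len(design$n_datasets)) {
      dat <- gen_dataset(design, r, sigma_u2 = s2)
      res <- tryCatch({
        naive <- suppressWarnings(
          stats::glm(y ~ w + I(w^2), family = binomial(), data = dat))
        est_n <- coef(naive)[3]
        se_n <- sqrt(diag(stats::vcov(naive)))[3]
        out <- list()
        if ("naive" %in% methods) {
          out$naive <- c(est = unname(est_n), se = unname(se_n))
        }
        if ("mcem" %in% methods) {
          fit <- mcem_refit(dat[c("y", "w")], y ~ w + I(w^2),
                            family = "binomial", error_cols = "w",
                            sigma_u = s2, B = B, epsilon = epsilon,
                            max_iter = max_iter,
                            seed = replicate_seed(design$seed, r, salt = 11L))
          out$mcem <- c(est = unname(fit$coefficients[3]),
                        se = unname(fit$se[3]))
        }
        out
      }, error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          method = "failed", sigma_u2 = s2, rep = r, est = NA_real_,
          se = NA_real_, note = conditionMessage(res))
        next
      }
      for (m in names(res)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          method = m, sigma_u2 = s2, rep = r, est = res[[m]]["est"],
          se = res[[m]]["se"], note = NA_character_)
      }
    }
  }
  reps <- dplyr::bind_rows(rows)
  ok <- dplyr::filter(reps, .data$method != "failed")
  summary <- ok |>
    dplyr::group_by(.data$method, .data$sigma_u2) |>
    dplyr::summarise(
      rel_bias = mean(.data$est - truth) / abs(truth),
      rmse = sqrt(mean((.data$est - truth)^2)),
      coverage = mean(.data$est - z * .data$se <= truth &
                        truth <= .data$est + z * .data$se),
      n_ok = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(n_fail = design$n_datasets - .data$n_ok)
  attr(summary, "replicates") <- reps
  attr(summary, "truth") <- truth
  summary
}

#' Prediction error on independent test data
#'
#' Evaluates the fitted linear predictor on fresh test covariates (optionally
#' shifted upward to mimic a distribution-shift scenario) against the true
#' linear predictor, reporting both the mean squared error
#' `sum (eta - eta_hat)^2 / n*` and its square root.
#'
#' @param fit A fitted model: an `mcem_fit`, any object with a
#'   `predict(fit, newdata, type = "link")` method (e.g. `glm`, `gam`), or a
#'   plain `function(newdata) -> eta_hat`.
#' @param test A [gen_dataset()] tibble (its attached design defines the
#'   true linear predictor), or any tibble with column `x` plus a `design`
#'   attribute.
#' @param shift Additive covariate shift applied to the test covariate
#'   before evaluation (0 or 0.5 in the benchmark experiments).
#' @param covariate Name of the model's covariate column (the test `x` is
#'   fed to the fit under this name; default `"w"`).
#' @return Tibble with columns `mean_sq` and `rmse`.
#' @export
prediction_rmse <- function(fit, test, shift = 0, covariate = "w") {
  design <- attr(test, "design")
  if (is.null(design)) stop("`test` must carry a \"design\" attribute.")
  xs <- test$x + shift
  eta <- true_eta(xs, design)
  nd <- stats::setNames(data.frame(xs), covariate)
  eta_hat <- if (is.function(fit)) {
    fit(nd)
  } else if (inherits(fit, "mcem_fit")) {
    predict(fit, newdata = nd, type = "link")
  } else {
    as.numeric(predict(fit, newdata = nd, type = "link"))
  }
  msq <- mean((eta - eta_hat)^2)
  tibble::tibble(mean_sq = msq, rmse = sqrt(msq))
}

#' Reliability ratio of a contaminated covariate
#'
#' `100 * (1 - sigma_u2 / sigma_w2)`: the percentage of the observed
#' covariate's variance attributable to the true covariate.
#'
#' @param sigma_u2 Measurement-error variance (`0 <= sigma_u2 <= sigma_w2`).
#' @param sigma_w2 Observed-covariate variance (`> 0`).
#' @return Percentage in `[0, 100]`.
#' @examples
#' reliability_ratio(0.0063, 0.0452) # 86.1
#' @export
reliability_ratio <- function(sigma_u2, sigma_w2) {
  if (sigma_w2 <= 0) stop("`sigma_w2` must be positive.")
  if (sigma_u2 < 0) stop("`sigma_u2` must be non-negative.")
  if (sigma_u2 > sigma_w2) {
    stop("`sigma_u2` exceeds `sigma_w2`: the reliability ratio would be negative.")
  }
  100 * (1 - sigma_u2 / sigma_w2)
}
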