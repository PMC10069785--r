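#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy the coefficients of a measurement-error-corrected fit
#'
#' @param x An `mcem_fit`.
#' @param conf.int Include Wald confidence-interval columns.
#' @param conf.level Interval level (defaults to the level stored in the
#'   fit).
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value` and optionally `conf.low`, `conf.high`.
#' @export
tidy.mcem_fit <- function(x, conf.int = TRUE, conf.level = NULL, ...) {
  level <- conf.level %||% x$conf_level %||% 0.95
  est <- x$coefficients
  se <- x$se
  stat <- est / se
  out <- tibble::tibble(
    term = names(est) %||% paste0("b", seq_along(est) - 1L),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = 2 * pnorm(-abs(unname(stat)))
  )
  if (conf.int) {
    z <- qnorm(1 - (1 - level) / 2)
    out$conf.low <- out$estimate - z * out$std.error
    out$conf.high <- out$estimate + z * out$std.error
  }
  out
}

#' One-row summary of a measurement-error-corrected fit
#'
#' @param x An `mcem_fit`.
#' @param ... Unused.
#' @return A one-row tibble: observed log-likelihood, AIC
#'   (`-2 loglik + 2 edf`), effective degrees of freedom, mean importance
#'   ESS, iteration count, convergence flag, `n`, `B`.
#' @export
glance.mcem_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    AIC = -2 * x$loglik + 2 * x$edf,
    edf = x$edf,
    ess_mean = x$ess_mean,
    n_iter = x$n_iter,
    converged = x$converged,
    nobs = x$nobs,
    B = x$B
  )
}

#' EM trace plot for a corrected fit
#'
#' Shows the observed log-likelihood ascent and the coefficient change per
#' EM iteration.
#'
#' @param object An `mcem_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mcem_fit <- function(object, ...) {
  tr <- object$trace |>
    tidyr::pivot_longer(c("loglik", "delta"), names_to = "quantity")
  labs <- c(loglik = "observed log-likelihood",
            delta = "max relative coefficient change")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iter, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~quantity, scales = "free_y",
                        labeller = ggplot2::as_labeller(labs)) +
    ggplot2::labs(x = "EM iteration", y = NULL,
                  title = "Monte Carlo EM trace") +
    ggplot2::theme_minimal()
}

#' Plot a simulation-study summary
#'
#' Relative bias, RMSE and coverage of the quadratic coefficient against the
#' measurement-error variance, one line per method.
#'
#' @param summary A [run_sim_study()] result.
#' @param conf_level Nominal coverage level drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_sim_study <- function(summary, conf_level = 0.95) {
  long <- summary |>
    tidyr::pivot_longer(c("rel_bias", "rmse", "coverage"),
                        names_to = "metric")
  ref <- tibble::tibble(metric = "coverage", y = conf_level)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sigma_u2, y = .data$value,
                                     colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(data = ref, ggplot2::aes(yintercept = .data$y),
                        linetype = 2, colour = "grey40") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = expression(sigma[u]^2), y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
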