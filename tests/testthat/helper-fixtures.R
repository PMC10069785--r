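# Shared fixtures, all built in code.

# logistic-quadratic data with classical error on the covariate
make_logistic_data <- function(n = 300, sigma_u2 = 0.25, seed = 1,
                               beta = c(0.5, 1, -0.3)) {
  set.seed(seed)
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(beta[1] + beta[2] * x + beta[3] * x^2))
  w <- x + rnorm(n, sd = sqrt(sigma_u2))
  data.frame(y = y, x = x, w = w)
}

# hand-rolled imputation_set for oracle tests
manual_imps <- function(values, cols = "x") {
  B <- length(values)
  n <- nrow(values[[1]])
  p <- ncol(values[[1]])
  values <- lapply(values, function(v) {
    colnames(v) <- cols
    v
  })
  structure(list(values = values, draws = values, B = B, n = n, p = p,
                 seed = 0L, cols = cols),
            class = "imputation_set")
}

# weight matrix with the package's class
manual_weights <- function(q) {
  structure(q / rowSums(q), class = c("weight_matrix", "matrix", "array"))
}

# simulate capture histories for a population of size N with
# p_i = plogis(b0 + b1 x_i); returns only ever-captured individuals
simulate_captures <- function(N = 500, tau = 5, b = c(-1, 0.8),
                              sigma_u2 = 0.35, seed = 1) {
  set.seed(seed)
  x <- rnorm(N, mean = 0, sd = 1)
  p <- plogis(b[1] + b[2] * x)
  H <- matrix(rbinom(N * tau, 1, rep(p, tau)), N, tau)
  caught <- rowSums(H) > 0
  w <- x + rnorm(N, sd = sqrt(sigma_u2))
  list(histories = H[caught, , drop = FALSE], x = x[caught],
       w = w[caught], N = N, tau = tau)
}

# inhomogeneous Poisson pattern on a rectangle with log-intensity
# b0 + b1 * cov(s); cell covariate values are standard normal so the
# structural normal prior of the corrected fits is well specified
simulate_ppm <- function(b = c(-1.5, 0.8), window = c(0, 10, 0, 10),
                         res = 0.5, seed = 1, sigma_u2 = 0) {
  set.seed(seed)
  gx <- seq(window[1] + res / 2, window[2], by = res)
  gy <- seq(window[3] + res / 2, window[4], by = res)
  raster <- expand.grid(x = gx, y = gy)
  raster$temp <- rnorm(nrow(raster))
  if (sigma_u2 > 0) raster$temp <- raster$temp + rnorm(nrow(raster), sd = sqrt(sigma_u2))
  lam <- exp(b[1] + b[2] * raster$temp)
  cell_area <- res^2
  counts <- rpois(nrow(raster), lam * cell_area)
  idx <- rep(seq_len(nrow(raster)), counts)
  jitter <- function(n) (runif(n) - 0.5) * res
  pres <- data.frame(x = raster$x[idx] + jitter(length(idx)),
                     y = raster$y[idx] + jitter(length(idx)))
  pres$x <- pmin(pmax(pres$x, window[1] + 1e-9), window[2] - 1e-9)
  pres$y <- pmin(pmax(pres$y, window[3] + 1e-9), window[4] - 1e-9)
  list(presences = pres, raster = raster, window = window, b = b)
}
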