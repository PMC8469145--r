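# Shared fixtures: built in code, deterministic.

default_model <- function() gaussian_model(1, 1, 1)

# Random symmetric positive-definite matrix (for precision-flow identities).
random_spd <- function(n = 3) {
  M <- matrix(stats::rnorm(n * n), n, n)
  crossprod(M) + diag(n) * 0.5
}

# Random positive scalars for property-style loops over parameterizations.
random_params <- function() {
  list(gamma = stats::runif(1, 0.2, 3),
       theta = stats::runif(1, 0.2, 3),
       kappa = stats::runif(1, 0.2, 3))
}

# Gaussian sampler via the Cholesky trick (for Monte-Carlo plug-in checks).
rmvn <- function(n, mean, Sigma) {
  z <- matrix(stats::rnorm(n * length(mean)), n)
  sweep(z %*% chol(Sigma), 2, mean, `+`)
}

# 2-d quadrature estimate of a Gaussian KL on a wide regular grid:
# independent slow oracle for the closed form.
kl_quadrature_2d <- function(mode_a, cov_a, mode_b, cov_b, half_width = 8,
                             n_grid = 401) {
  sds <- sqrt(diag(cov_a))
  xs <- seq(mode_a[1] - half_width * sds[1], mode_a[1] + half_width * sds[1],
            length.out = n_grid)
  ys <- seq(mode_a[2] - half_width * sds[2], mode_a[2] + half_width * sds[2],
            length.out = n_grid)
  dx <- diff(xs)[1]; dy <- diff(ys)[1]
  Pa <- solve(cov_a); Pb <- solve(cov_b)
  lda <- determinant(cov_a, logarithm = TRUE)$modulus
  ldb <- determinant(cov_b, logarithm = TRUE)$modulus
  grid <- as.matrix(expand.grid(x = xs, y = ys))
  da <- sweep(grid, 2, mode_a)
  db <- sweep(grid, 2, mode_b)
  lp <- -0.5 * (rowSums((da %*% Pa) * da) + lda + 2 * log(2 * pi))
  lq <- -0.5 * (rowSums((db %*% Pb) * db) + ldb + 2 * log(2 * pi))
  sum(exp(lp) * (lp - lq)) * dx * dy
}
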