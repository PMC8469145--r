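test_that("Gaussian KL closed form matches hand values and quadrature", {
  expect_equal(gaussian_kl(0, matrix(1), 0, matrix(1)), 0)
  expect_equal(gaussian_kl(0, matrix(1), 1, matrix(1)), 0.5)
  expect_equal(gaussian_kl(0, matrix(2), 0, matrix(1)), (2 - 1 + log(1 / 2)) / 2,
               tolerance = 1e-12)
  expect_equal(gaussian_kl(0, matrix(1), 0, matrix(2)), (1 / 2 - 1 + log(2)) / 2,
               tolerance = 1e-12)
  # 1-d quadrature oracle
  cases <- list(c(0, 1, 1, 1), c(0, 2, 0, 1), c(-1, 0.5, 2, 3))
  for (cs in cases) {
    expect_equal(gaussian_kl(cs[1], matrix(cs[2]), cs[3], matrix(cs[4])),
                 kl_quadrature_1d(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-6)
  }
  # 2-d quadrature oracle
  A <- matrix(c(1, 0.3, 0.3, 0.8), 2, 2)
  B <- matrix(c(1.5, -0.2, -0.2, 1.2), 2, 2)
  expect_equal(gaussian_kl(c(0, 0), A, c(0.5, -0.3), B),
               kl_quadrature_2d(c(0, 0), A, c(0.5, -0.3), B),
               tolerance = 1e-4)
  expect_error(gaussian_kl(0, matrix(1), c(0, 0), diag(2)), "dimension")
})

test_that("the blanket-conditioned covariance is the Schur complement with the stated values", {
  m <- default_model()
  S <- stationary_covariance(m)
  U <- conditional_covariance(S)
  expect_equal(U[1, 2], 0, tolerance = 1e-14)      # blanket condition
  expect_equal(U[1, 1], 1 / 2, tolerance = 1e-14)  # 3/4 - (1/4)/1... Schur value
  # block-diagonal in b vs (mu, eta): conditioning changes nothing
  S_bd <- diag(3); S_bd[1, 3] <- S_bd[3, 1] <- 0.4
  U_bd <- conditional_covariance(S_bd)
  expect_equal(matrix(U_bd, 2, 2), S_bd[c(1, 3), c(1, 3)])
})

test_that("conditional mutual information has the Gaussian closed form and invariances", {
  m <- default_model()
  expect_equal(conditional_mutual_information(stationary_covariance(m)), 0)
  # scalar conditional correlation rho = 0.5
  S <- diag(3)
  S[1, 3] <- S[3, 1] <- 0.5
  expect_equal(conditional_mutual_information(S), -0.5 * log(0.75),
               tolerance = 1e-12)
  # invariance under separate rescaling of mu and eta
  set.seed(13)
  for (i in 1:10) {
    Sig <- random_spd()
    D <- diag(c(stats::runif(1, 0.1, 5), 1, stats::runif(1, 0.1, 5)))
    expect_equal(conditional_mutual_information(D %*% Sig %*% D),
                 conditional_mutual_information(Sig), tolerance = 1e-10)
  }
})

test_that("closed-form CMI agrees with a Monte-Carlo plug-in estimate", {
  set.seed(17)
  Sig <- matrix(c(1, 0.4, 0.3,
                  0.4, 1.2, -0.2,
                  0.3, -0.2, 0.9), 3, 3)
  truth <- conditional_mutual_information(Sig)
  n_blocks <- 10; n_per <- 1e5
  est <- vapply(seq_len(n_blocks), function(b) {
    X <- rmvn(n_per, c(0, 0, 0), Sig)
    conditional_mutual_information(stats::cov(X))
  }, 0)
  se <- stats::sd(est) / sqrt(n_blocks)
  expect_lt(abs(mean(est) - truth), 3 * se + 1e-4)
})

test_that("information length accumulates sqrt(2 KL) and is exact for translations", {
  # explicit-divergence route
  states <- list(1, 2, 3)
  kl_const <- function(new, old) 0.02
  l <- information_length(states, kl_const)
  expect_equal(l, c(0, 0.2, 0.4), tolerance = 1e-12)
  # an exactly constant trajectory has exactly zero length
  m <- default_model()
  S_inf <- stationary_covariance(m)
  tr <- structure(list(times = seq(0, 1, by = 0.25),
                       modes = matrix(0, 5, 3),
                       covariances = array(S_inf, c(3, 3, 5)),
                       dt = 0.25, state_names = c("mu", "b", "eta")),
                  class = "density_trajectory")
  il <- information_length(tr)
  # each increment is sqrt(2 * KL) with KL at round-off (~1e-15), so the
  # accumulated length sits at the sqrt of round-off, not exactly zero
  expect_lt(max(il$il_joint), 1e-6)
  # near-stationary numerical trajectory stays numerically negligible
  tr2 <- propagate_density(m, density_state(m$theta_mode, S_inf),
                           dt = 1 / 32, T = 1)
  expect_lt(max(information_length(tr2)$il_joint), 1e-5)
  # translation family: mode moves distance d at fixed variance -> length d / sigma
  sigma2 <- 0.49; d <- 2
  for (K in c(64, 128)) {
    modes <- seq(0, d, length.out = K + 1)
    states <- lapply(modes, function(mu) list(mode = mu, var = sigma2))
    kl_g <- function(new, old) gaussian_kl(new$mode, matrix(new$var),
                                           old$mode, matrix(old$var))
    total <- tail(information_length(states, kl_g), 1)
    expect_equal(total, d / sqrt(sigma2), tolerance = 0.01)
  }
  # invariance under affine reparameterization of the state (scaling by c)
  c_scale <- 3.7
  modes <- seq(0, d, length.out = 65)
  states_raw <- lapply(modes, function(mu) list(mode = mu, var = sigma2))
  states_scaled <- lapply(modes, function(mu) list(mode = c_scale * mu,
                                                   var = c_scale^2 * sigma2))
  kl_g <- function(new, old) gaussian_kl(new$mode, matrix(new$var),
                                         old$mode, matrix(old$var))
  expect_equal(tail(information_length(states_raw, kl_g), 1),
               tail(information_length(states_scaled, kl_g), 1),
               tolerance = 1e-10)
})

test_that("information length along the observed-blanket relaxation is monotone and refines", {
  m <- default_model()
  il64 <- information_length(propagate_density(m, perturbed_initial_density(m),
                                               dt = 1 / 64, T = 16))
  expect_true(all(diff(il64$il_joint) >= -1e-12))
  expect_true(all(diff(il64$il_blanket) >= -1e-12))
  il128 <- information_length(propagate_density(m, perturbed_initial_density(m),
                                                dt = 1 / 128, T = 16))
  expect_lt(abs(tail(il64$il_joint, 1) - tail(il128$il_joint, 1)) /
              tail(il128$il_joint, 1), 0.01)
})

test_that("conditional MI along the relaxation is nonnegative, starts at zero, peaks then decays", {
  m <- default_model()
  tr <- propagate_density(m, perturbed_initial_density(m), dt = 1 / 64, T = 16)
  ms <- measure_series(m, tr)
  cmi <- ms$measures$cmi
  expect_true(all(cmi >= 0))
  expect_equal(cmi[1], 0, tolerance = 1e-10)
  expect_gt(max(cmi), 0.01)
  expect_lt(tail(cmi, 1), 1e-6)
  expect_gt(which.max(cmi), 1)
})

test_that("time constants are reciprocals of eigenvalue real-part magnitudes", {
  expect_equal(as.numeric(time_constants(diag(c(-2, -4)))), c(0.5, 0.25))
  # complex pair -1 +/- 3i: rotation block
  J <- matrix(c(-1, 3, -3, -1), 2, 2)
  expect_equal(as.numeric(time_constants(J)), c(1, 1))
  # zero modes excluded and counted
  tc <- time_constants(diag(c(-2, 0)))
  expect_equal(as.numeric(tc), 0.5)
  expect_equal(attr(tc, "n_zero_modes"), 1L)
  tc_cov <- time_constants(covariance_jacobian(default_model()))
  expect_true(all(is.finite(tc_cov)) && all(tc_cov > 0))
})

test_that("categorical KL has the discrete closed forms and Gibbs inequality", {
  expect_equal(categorical_kl(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(categorical_kl(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_error(categorical_kl(c(1, 0), c(0, 1)), "support")
  expect_error(categorical_kl(c(0.5, 0.6), c(0.5, 0.5)), "sum to 1")
  set.seed(23)
  for (i in 1:20) {
    p <- stats::runif(5); p <- p / sum(p)
    q <- stats::runif(5); q <- q / sum(q)
    expect_gte(categorical_kl(p, q), 0)
  }
})

test_that("categorical conditional MI is zero iff the tensor factorizes given the blanket", {
  set.seed(29)
  # random factorized tensor -> exactly zero
  s_b <- stats::runif(3); s_b <- s_b / sum(s_b)
  A <- matrix(stats::runif(9), 3); A <- sweep(A, 2, colSums(A), "/")
  B <- matrix(stats::runif(9), 3); B <- sweep(B, 2, colSums(B), "/")
  s <- array(0, c(3, 3, 3))
  for (b in 1:3) s[, b, ] <- s_b[b] * outer(A[, b], B[, b])
  expect_equal(categorical_cmi(s), 0, tolerance = 1e-14)
  # the construction-by-factorization steady state
  cm <- categorical_model()
  expect_equal(categorical_cmi(cm$s_joint_inf), 0, tolerance = 1e-14)
  # perfect correlation given a single blanket state: one bit (in nats)
  s2 <- array(0, c(2, 1, 2))
  s2[1, 1, 1] <- 0.5; s2[2, 1, 2] <- 0.5
  expect_equal(categorical_cmi(s2), log(2), tolerance = 1e-12)
  expect_error(categorical_cmi(array(-1, c(2, 2, 2))), "negative")
})
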