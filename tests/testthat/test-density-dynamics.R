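test_that("the observed-blanket initial density only raises the blanket precision", {
  m <- default_model()
  st <- perturbed_initial_density(m)
  Phi0 <- precision_of(st)
  expect_equal(Phi0[2, 2], exp(4), tolerance = 1e-10)
  off <- m$hessian; off[2, 2] <- 0
  check <- Phi0; check[2, 2] <- 0
  expect_equal(check, off, tolerance = 1e-10)
  # conditional density p(mu, eta | b) untouched => CMI starts at zero
  expect_equal(conditional_mutual_information(st$covariance), 0)
  # blanket variance pinned far below the stationary value of 1
  expect_lt(st$covariance[2, 2], 1 / (exp(4) - 2))
  # additive variant barely differs at this magnitude
  st_add <- perturbed_initial_density(m, additive = TRUE)
  expect_lt(max(abs(st_add$covariance - st$covariance)), 1e-3)
})

test_that("the stationary density is a fixed point of the propagation", {
  m <- default_model()
  st <- density_state(m$theta_mode, stationary_covariance(m))
  tr <- propagate_density(m, st, dt = 1 / 64, T = 16)
  nt <- length(tr$times)
  expect_lt(max(abs(tr$modes)), 1e-8)
  expect_lt(max(abs(tr$covariances[, , nt] - stationary_covariance(m))), 1e-8)
})

test_that("RK4 propagation matches the matrix-exponential closed form", {
  m <- default_model()
  # near-point-mass mode trajectory: the linear mean ODE in closed form
  st <- density_state(c(1, 1, 1), diag(3) * 1e-6)
  tr <- propagate_density(m, st, dt = 1 / 256, T = 8)
  A <- (m$diffusion - m$solenoidal) %*% m$hessian
  for (t in c(1, 4, 8)) {
    i <- which.min(abs(tr$times - t))
    expect_equal(tr$modes[i, ], as.numeric(Matrix::expm(-A * t) %*% c(1, 1, 1)),
                 tolerance = 1e-8)
  }
  # full affine system against the expm oracle from the protocol densities
  # at the production step
  for (st0 in list(perturbed_initial_density(m),
                   density_state(c(1, 1, 1), diag(3) * 1e-6))) {
    tri <- propagate_density(m, st0, dt = 1 / 64, T = 4)
    oracle <- propagate_density_expm(m, st0, times = c(1, 2.5, 4))
    for (j in seq_along(oracle$times)) {
      i <- which.min(abs(tri$times - oracle$times[j]))
      expect_equal(tri$modes[i, ], oracle$modes[j, ], tolerance = 1e-6)
      expect_lt(max(abs(tri$covariances[, , i] - oracle$covariances[, , j])),
                1e-6)
    }
  }
  # arbitrary (larger-amplitude) initial conditions and parameters: the
  # fixed-step truncation error scales as dt^4, so a finer grid recovers
  # the same agreement
  set.seed(21)
  for (p in list(list(1, 1, 1), list(0.5, 2, 0.7))) {
    mi <- gaussian_model(p[[1]], p[[2]], p[[3]])
    st0 <- density_state(stats::rnorm(3), random_spd())
    tri <- propagate_density(mi, st0, dt = 1 / 256, T = 4)
    oracle <- propagate_density_expm(mi, st0, times = c(1, 2.5, 4))
    for (j in seq_along(oracle$times)) {
      i <- which.min(abs(tri$times - oracle$times[j]))
      expect_equal(tri$modes[i, ], oracle$modes[j, ], tolerance = 1e-6)
      expect_lt(max(abs(tri$covariances[, , i] - oracle$covariances[, , j])),
                1e-6)
    }
  }
})

test_that("covariance Jacobian has the Kronecker structure, trace and stable spectrum", {
  m <- default_model()
  J <- covariance_jacobian(m)
  expect_equal(dim(J), c(9, 9))
  expect_equal(sum(diag(J)), -9, tolerance = 1e-12)
  ev <- eigen(J, only.values = TRUE)$values
  expect_true(all(Re(ev) <= 1e-12))
  # against a finite difference of the flow on a random symmetric direction
  set.seed(4)
  S <- random_spd(); E <- random_spd() - random_spd()
  A <- (m$diffusion - m$solenoidal) %*% m$hessian
  flow <- function(S) 2 * m$diffusion - A %*% S - S %*% t(A)
  h <- 1e-6
  fd <- (flow(S + h * E) - flow(S)) / h
  expect_equal(as.numeric(fd), as.numeric(matrix(J %*% as.numeric(E), 3, 3)),
               tolerance = 1e-6)
})

test_that("precision rate vanishes at steady state and matches the covariance flow image", {
  m <- default_model()
  expect_lt(max(abs(precision_rate(m, m$hessian))), 1e-12)
  expect_error(precision_rate(m, matrix(1:9, 3, 3)), "symmetric")
  A <- (m$diffusion - m$solenoidal) %*% m$hessian
  set.seed(31)
  for (i in 1:25) {
    Phi <- random_spd()
    S <- solve(Phi)
    Sdot <- 2 * m$diffusion - A %*% S - S %*% t(A)
    expect_lt(max(abs(precision_rate(m, Phi) + Phi %*% Sdot %*% Phi)), 1e-10)
  }
})

test_that("the labelled scalar decomposition reproduces the matrix precision rate", {
  set.seed(41)
  for (i in 1:25) {
    p <- random_params()
    m <- gaussian_model(p$gamma, p$theta, p$kappa)
    Phi <- random_spd()
    dec <- precision_rate_mu_eta(m, Phi)
    expect_equal(unname(dec["total"]), precision_rate(m, Phi)[1, 3],
                 tolerance = 1e-12)
  }
  # all groups, including the solenoidal one, vanish at steady state
  m <- gaussian_model(0.7, 1.8, 1.3)
  dec0 <- precision_rate_mu_eta(m, m$hessian)
  expect_equal(unname(dec0), c(0, 0, 0, 0), tolerance = 1e-12)
  # diagonal precision: blanket-dissipation reduces to its sqrt(kappa) terms
  Phi_d <- diag(c(1.2, 2.5, 0.8))
  dec_d <- precision_rate_mu_eta(m, Phi_d)
  expect_equal(unname(dec_d["dissipation_blanket"]), 0)
  expect_equal(unname(dec_d["solenoidal"]),
               m$theta * sqrt(m$kappa) * (1.2 - 0.8), tolerance = 1e-12)
  expect_equal(unname(dec_d["total"]), precision_rate(m, Phi_d)[1, 3],
               tolerance = 1e-12)
})

test_that("inverting the covariance trajectory agrees with direct precision integration", {
  m <- default_model()
  st <- perturbed_initial_density(m)
  # the imposed blanket precision (~54.6) relaxes on a time scale of
  # 1/(2 Phi_bb^2 Gamma_bb) ~ 1e-3, so the direct precision integration
  # needs a step resolving that initial layer
  dt <- 1 / 1024
  tr <- propagate_density(m, st, dt = dt, T = 4)
  Phi_direct <- propagate_precision(m, precision_of(st), dt = dt, T = 4)
  Phi_inv <- precision_trajectory(tr)
  expect_lt(max(abs(Phi_inv - Phi_direct)), 1e-5)
})

test_that("the blanket condition is transiently violated then restored after observation", {
  m <- default_model()
  tr <- propagate_density(m, perturbed_initial_density(m), dt = 1 / 64, T = 16)
  Phi <- precision_trajectory(tr)
  phi_me <- Phi[1, 3, ]
  expect_equal(phi_me[1], 0, tolerance = 1e-12)          # blanket holds at tau = 0
  expect_gt(max(abs(phi_me)), 0.01)                      # transient dependence
  expect_lt(abs(phi_me[length(phi_me)]), 1e-3)           # restored by tau = 16
  # decaying oscillation: at least one sign change, later extrema smaller
  expect_gte(sum(diff(sign(phi_me[abs(phi_me) > 1e-8])) != 0), 1)
  half <- length(phi_me) %/% 2
  expect_gt(max(abs(phi_me[1:half])), max(abs(phi_me[(half + 1):length(phi_me)])))
})

test_that("propagation rejects invalid states and steps", {
  m <- default_model()
  expect_error(density_state(c(0, 0, 0), diag(c(1, -1, 1))), "positive-definite")
  st <- density_state(m$theta_mode, stationary_covariance(m))
  expect_error(propagate_density(m, st, dt = -1), "dt")
})
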