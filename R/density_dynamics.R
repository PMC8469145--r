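#' A Gaussian density state
#'
#' One point on the statistical manifold: a multivariate normal with mode
#' `mode`, covariance `covariance`, tagged with a time.
#'
#' @param mode numeric mode vector (xi).
#' @param covariance symmetric positive-definite covariance (Sigma).
#' @param time scalar time stamp (tau).
#' @return An object of class `density_state`.
#' @export
density_state <- function(mode, covariance, time = 0) {
  mode <- as.numeric(mode)
  covariance <- unname(as.matrix(covariance))
  if (nrow(covariance) != length(mode))
    stop("mode and covariance dimensions disagree", call. = FALSE)
  if (max(abs(covariance - t(covariance))) > 1e-8)
    stop("covariance must be symmetric", call. = FALSE)
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("covariance must be positive-definite", call. = FALSE)
  structure(list(mode = mode, covariance = (covariance + t(covariance)) / 2,
                 time = time),
            class = "density_state")
}

#' @export
print.density_state <- function(x, ...) {
  cat(sprintf("<density_state> tau = %g, mode = (%s)\n", x$time,
              paste(signif(x$mode, 4), collapse = ", ")))
  invisible(x)
}

#' Precision matrix of a density state
#'
#' @param state a `density_state`.
#' @return The inverse covariance (symmetrized).
#' @export
precision_of <- function(state) {
  P <- solve(state$covariance)
  (P + t(P)) / 2
}

#' Initial density with an observed (high-precision) blanket state
#'
#' Constructs the perturbation protocol used throughout the continuous
#' simulations: a density consistent with steady state except that the
#' precision of the blanket state is set very high (exp(4) by default), as
#' if the blanket had just been observed at its expected value. Only the
#' (b, b) entry of the precision differs from the steady-state Hessian, so
#' the conditional density p(mu, eta | b) is unchanged and the conditional
#' mutual information starts at exactly zero.
#'
#' @param m a [gaussian_model()].
#' @param log_precision natural log of the imposed blanket precision
#'   (default 4, i.e. precision exp(4) ~ 54.6).
#' @param additive if `TRUE`, add `exp(log_precision)` to the steady-state
#'   (b, b) precision instead of replacing it. At the default magnitude the
#'   two differ negligibly.
#' @return A `density_state` at time 0.
#' @export
perturbed_initial_density <- function(m, log_precision = 4,
                                      additive = FALSE) {
  stopifnot(inherits(m, "gaussian_model"))
  b <- m$partition$blanket
  Phi0 <- m$hessian
  Phi0[b, b] <- if (additive) Phi0[b, b] + exp(log_precision) else exp(log_precision)
  ev <- eigen(Phi0, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("perturbed precision is not positive-definite", call. = FALSE)
  density_state(m$theta_mode, solve(Phi0), time = 0)
}

#' Propagate the Gaussian density dynamics
#'
#' Integrates the coupled mode/covariance flow of the Fokker-Planck
#' equation under the Laplace assumption,
#' \deqn{\dot\xi = -A(\xi - \vartheta), \quad
#'       \dot\Sigma = 2\Gamma - A\Sigma - \Sigma A^\top,}
#' with `A = (Gamma - Q) Pi`, using fixed-step classical Runge-Kutta (RK4).
#' The covariance is re-symmetrized after every step. The stationary point
#' is `(theta_mode, solve(hessian))`.
#'
#' @param m a [gaussian_model()].
#' @param state0 initial `density_state`.
#' @param dt integration step (default 1/64).
#' @param T horizon.
#' @return An object of class `density_trajectory`: `times`, `modes`
#'   (matrix `n_t x 3`), `covariances` (array `3 x 3 x n_t`), `dt`.
#' @examples
#' m <- gaussian_model()
#' tr <- propagate_density(m, perturbed_initial_density(m), T = 16)
#' @export
propagate_density <- function(m, state0, dt = 1 / 64, T = 16) {
  stopifnot(inherits(m, "gaussian_model"), inherits(state0, "density_state"))
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  A <- drift_matrix(m)
  G2 <- 2 * m$diffusion
  th <- m$theta_mode
  n_steps <- round(T / dt)
  times <- state0$time + seq(0, by = dt, length.out = n_steps + 1)

  n <- length(th)
  modes <- matrix(NA_real_, n_steps + 1, n)
  covs <- array(NA_real_, dim = c(n, n, n_steps + 1))
  xi <- state0$mode
  S <- state0$covariance
  modes[1, ] <- xi
  covs[, , 1] <- S

  f_xi <- function(x) -A %*% (x - th)
  f_S <- function(S) G2 - A %*% S - S %*% t(A)
  for (s in seq_len(n_steps)) {
    k1x <- f_xi(xi);             k1S <- f_S(S)
    k2x <- f_xi(xi + dt / 2 * k1x); k2S <- f_S(S + dt / 2 * k1S)
    k3x <- f_xi(xi + dt / 2 * k2x); k3S <- f_S(S + dt / 2 * k2S)
    k4x <- f_xi(xi + dt * k3x);     k4S <- f_S(S + dt * k3S)
    xi <- as.numeric(xi + dt / 6 * (k1x + 2 * k2x + 2 * k3x + k4x))
    S <- S + dt / 6 * (k1S + 2 * k2S + 2 * k3S + k4S)
    S <- (S + t(S)) / 2
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop(sprintf("covariance lost positive-definiteness at step %d; try a smaller dt", s),
           call. = FALSE)
    modes[s + 1, ] <- xi
    covs[, , s + 1] <- S
  }
  structure(list(times = times, modes = modes, covariances = covs, dt = dt,
                 state_names = c("mu", "b", "eta")),
            class = "density_trajectory")
}

#' @export
print.density_trajectory <- function(x, ...) {
  cat(sprintf("<density_trajectory> %d states over tau = [%g, %g], dt = %g\n",
              length(x$times), min(x$times), max(x$times), x$dt))
  invisible(x)
}

#' Extract one density state from a trajectory
#'
#' @param traj a `density_trajectory`.
#' @param t requested time (snapped to the nearest grid point).
#' @return A `density_state`.
#' @export
density_at <- function(traj, t) {
  stopifnot(inherits(traj, "density_trajectory"))
  i <- which.min(abs(traj$times - t))
  density_state(traj$modes[i, ], traj$covariances[, , i], traj$times[i])
}

#' Precision series along a density trajectory
#'
#' @param traj a `density_trajectory`.
#' @return Array `3 x 3 x n_t` of inverse covariances.
#' @export
precision_trajectory <- function(traj) {
  stopifnot(inherits(traj, "density_trajectory"))
  out <- array(NA_real_, dim = dim(traj$covariances))
  for (i in seq_along(traj$times)) {
    P <- solve(traj$covariances[, , i])
    out[, , i] <- (P + t(P)) / 2
  }
  out
}

#' Jacobian of the vectorized covariance flow
#'
#' The covariance obeys the Sylvester-type linear system
#' `vec(dSigma/dt) = -(A \%x\% I + I \%x\% A) vec(Sigma) + 2 vec(Gamma)`
#' under column-stacking vectorization, with `A = (Gamma - Q) Pi`. The
#' returned matrix is the homogeneous part; its eigenvalue real parts set
#' the decay time constants of the covariance dynamics (see
#' [time_constants()]).
#'
#' @param m a [gaussian_model()].
#' @return The `n^2 x n^2` matrix `-(A \%x\% I + I \%x\% A)`.
#' @export
covariance_jacobian <- function(m) {
  stopifnot(inherits(m, "gaussian_model"))
  A <- drift_matrix(m)
  I <- diag(nrow(A))
  -(kronecker(A, I) + kronecker(I, A))
}

#' Instantaneous rate of change of the precision matrix
#'
#' The precision `Phi = solve(Sigma)` obeys
#' `dPhi/dt = Pi (Gamma - Q)^T Phi + Phi (Gamma - Q) Pi - 2 Phi Gamma Phi`,
#' the image of the covariance flow under `d(Sigma^-1) = -Phi dSigma Phi`.
#' At `Phi = Pi` the rate vanishes (steady state).
#'
#' @param m a [gaussian_model()].
#' @param Phi symmetric positive-definite precision matrix, or a
#'   `density_state` (whose precision is used).
#' @return Symmetric matrix of the same dimension.
#' @export
precision_rate <- function(m, Phi) {
  stopifnot(inherits(m, "gaussian_model"))
  if (inherits(Phi, "density_state")) Phi <- precision_of(Phi)
  Phi <- unname(as.matrix(Phi))
  if (max(abs(Phi - t(Phi))) > 1e-8)
    stop("Phi must be symmetric", call. = FALSE)
  B <- m$diffusion - m$solenoidal
  R <- m$hessian %*% t(B) %*% Phi + Phi %*% B %*% m$hessian -
    2 * Phi %*% m$diffusion %*% Phi
  (R + t(R)) / 2
}

#' Labelled decomposition of the internal-external precision rate
#'
#' For the standard three-state parameterization, the rate of change of the
#' precision entry coupling internal and external states splits into three
#' interpretable contributions:
#' \itemize{
#'   \item dissipation via the internal and external channels,
#'     `gamma * (kappa - (Phi_mm + Phi_ee)/2) * Phi_me`;
#'   \item dissipation via the blanket channel,
#'     `(sqrt(kappa) * (Phi_be + Phi_bm) - 2 * Phi_mb * Phi_be) / 4`;
#'   \item solenoidal coupling to the blanket,
#'     `theta * (2*kappa*(Phi_mb - Phi_be) + sqrt(kappa)*(Phi_mm - Phi_ee))`.
#' }
#' Their sum equals the (mu, eta) entry of [precision_rate()] identically.
#' At steady state (`Phi` equal to the Hessian) every group vanishes, so in
#' particular the solenoidal terms cancel.
#'
#' @param m a [gaussian_model()] built by the standard parameterization
#'   (finite gamma/theta/kappa tags; scalar partition cells).
#' @param Phi symmetric precision matrix or `density_state`.
#' @return Named numeric vector with elements
#'   `dissipation_internal_external`, `dissipation_blanket`, `solenoidal`,
#'   `total`.
#' @export
precision_rate_mu_eta <- function(m, Phi) {
  stopifnot(inherits(m, "gaussian_model"))
  p <- m$partition
  if (length(p$internal) != 1L || length(p$blanket) != 1L ||
      length(p$external) != 1L)
    stop("scalar decomposition requires one-dimensional partition cells",
         call. = FALSE)
  if (!is.finite(m$gamma))
    stop("decomposition requires the standard (gamma, theta, kappa) parameterization",
         call. = FALSE)
  if (inherits(Phi, "density_state")) Phi <- precision_of(Phi)
  Phi <- unname(as.matrix(Phi))
  i <- p$internal; b <- p$blanket; e <- p$external
  g <- m$gamma; th <- m$theta; k <- m$kappa; sk <- sqrt(k)
  Pmm <- Phi[i, i]; Pee <- Phi[e, e]; Pme <- Phi[i, e]
  Pmb <- Phi[i, b]; Pbe <- Phi[b, e]
  d_ie <- g * (k - (Pmm + Pee) / 2) * Pme
  d_b <- (sk * (Pbe + Pmb) - 2 * Pmb * Pbe) / 4
  sol <- th * (2 * k * (Pmb - Pbe) + sk * (Pmm - Pee))
  c(dissipation_internal_external = d_ie,
    dissipation_blanket = d_b,
    solenoidal = sol,
    total = d_ie + d_b + sol)
}

#' Integrate the precision flow directly
#'
#' RK4 integration of `dPhi/dt` from [precision_rate()]; used to cross-check
#' the covariance route (inverting [propagate_density()] output).
#'
#' @param m a [gaussian_model()].
#' @param Phi0 initial symmetric positive-definite precision.
#' @param dt step; `T` horizon.
#' @param T horizon.
#' @return Array `3 x 3 x n_t` plus a `times` attribute.
#' @export
propagate_precision <- function(m, Phi0, dt = 1 / 64, T = 16) {
  stopifnot(inherits(m, "gaussian_model"))
  Phi <- unname(as.matrix(Phi0))
  n_steps <- round(T / dt)
  out <- array(NA_real_, dim = c(nrow(Phi), ncol(Phi), n_steps + 1))
  out[, , 1] <- Phi
  for (s in seq_len(n_steps)) {
    k1 <- precision_rate(m, Phi)
    k2 <- precision_rate(m, Phi + dt / 2 * k1)
    k3 <- precision_rate(m, Phi + dt / 2 * k2)
    k4 <- precision_rate(m, Phi + dt * k3)
    Phi <- Phi + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    Phi <- (Phi + t(Phi)) / 2
    out[, , s + 1] <- Phi
  }
  attr(out, "times") <- seq(0, by = dt, length.out = n_steps + 1)
  out
}

#' Tidy view of a density trajectory
#'
#' @param traj a `density_trajectory`.
#' @return A data.frame with the mode, the six unique covariance entries and
#'   the six unique precision entries at each time.
#' @export
density_as_data_frame <- function(traj) {
  stopifnot(inherits(traj, "density_trajectory"))
  Phi <- precision_trajectory(traj)
  nt <- length(traj$times)
  pick <- function(Arr, i, j) vapply(seq_len(nt), function(s) Arr[i, j, s], 0)
  data.frame(
    time = traj$times,
    xi_mu = traj$modes[, 1], xi_b = traj$modes[, 2], xi_eta = traj$modes[, 3],
    sigma_mumu = pick(traj$covariances, 1, 1),
    sigma_mub = pick(traj$covariances, 1, 2),
    sigma_mueta = pick(traj$covariances, 1, 3),
    sigma_bb = pick(traj$covariances, 2, 2),
    sigma_beta = pick(traj$covariances, 2, 3),
    sigma_etaeta = pick(traj$covariances, 3, 3),
    phi_mumu = pick(Phi, 1, 1), phi_mub = pick(Phi, 1, 2),
    phi_mueta = pick(Phi, 1, 3), phi_bb = pick(Phi, 2, 2),
    phi_beta = pick(Phi, 2, 3), phi_etaeta = pick(Phi, 3, 3)
  )
}
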