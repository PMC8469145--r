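#' Seeded Euler-Maruyama ensemble simulation
#'
#' Integrates the stochastic differential equation
#' `dx = -(Gamma - Q) Pi (x - theta_mode) dt + dW`, with fluctuation
#' covariance `2 Gamma dt` per step, for `n_paths` independent paths from a
#' common initial state. Per-path noise streams are derived deterministically
#' from the root seed, so enlarging `n_paths` leaves existing paths
#' unchanged.
#'
#' @param m a [gaussian_model()].
#' @param x0 initial state vector (all paths start here).
#' @param n_paths number of independent sample paths (>= 1).
#' @param dt integration step (time units; > 0).
#' @param T horizon (>= dt).
#' @param seed integer root seed.
#' @param noise_scale multiplier on the fluctuation amplitude; 0 recovers
#'   the deterministic mean flow.
#' @param on_unstable what to do if the explicit Euler map `I - dt * A` has
#'   spectral radius >= 1 (the step is too large for the drift):
#'   `"warn"` (default) or `"error"`.
#' @return An object of class `ensemble_trajectories` with elements `times`
#'   (length `n_t`), `paths` (array `n_paths x n_t x 3`), `dt`, `seed`.
#' @examples
#' m <- gaussian_model()
#' tr <- simulate_ensemble(m, c(1, 1, 1), n_paths = 32, dt = 0.01, T = 2,
#'                         seed = 1)
#' ensemble_moments(tr, t = 2)$mean
#' @export
simulate_ensemble <- function(m, x0 = c(1, 1, 1), n_paths = 512, dt = 0.01,
                              T = 16, seed = 1, noise_scale = 1,
                              on_unstable = c("warn", "error")) {
  stopifnot(inherits(m, "gaussian_model"))
  on_unstable <- match.arg(on_unstable)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (T < dt) stop("horizon T must be at least dt", call. = FALSE)
  if (n_paths < 1) stop("need at least one path", call. = FALSE)
  x0 <- as.numeric(x0)
  n <- nrow(m$hessian)
  if (length(x0) != n) stop("x0 has wrong dimension", call. = FALSE)

  A <- drift_matrix(m)
  rho <- max(Mod(eigen(diag(n) - dt * A, only.values = TRUE)$values))
  if (rho >= 1) {
    msg <- sprintf("dt = %g is too large for stability (spectral radius %.3f >= 1)",
                   dt, rho)
    if (on_unstable == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }

  n_steps <- round(T / dt)
  times <- seq(0, by = dt, length.out = n_steps + 1)

  # Cholesky factor of the per-step noise covariance 2 * Gamma * dt.
  # pivot = TRUE tolerates semidefinite Gamma (e.g. a zero channel).
  ch <- suppressWarnings(chol(2 * dt * m$diffusion, pivot = TRUE))
  piv <- attr(ch, "pivot")
  Lns <- matrix(0, n, n)
  Lns[, piv] <- t(ch)
  Lns <- noise_scale * Lns

  # One deterministic noise stream per path, derived from the root seed so
  # that path k is identical whatever n_paths is.
  noise <- array(0, dim = c(n_paths, n_steps, n))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_paths, replace = TRUE)
  for (k in seq_len(n_paths)) {
    set.seed(seeds[k])
    z <- matrix(stats::rnorm(n_steps * n), n_steps, n)
    noise[k, , ] <- z %*% t(Lns)
  }

  paths <- array(NA_real_, dim = c(n_paths, n_steps + 1, n))
  X <- matrix(x0, n_paths, n, byrow = TRUE)
  paths[, 1, ] <- X
  shift <- matrix(m$theta_mode, n_paths, n, byrow = TRUE)
  for (s in seq_len(n_steps)) {
    X <- X - dt * (X - shift) %*% t(A) + noise[, s, ]
    paths[, s + 1, ] <- X
  }

  structure(
    list(times = times, paths = paths, dt = dt, seed = seed,
         state_names = c("mu", "b", "eta")),
    class = "ensemble_trajectories"
  )
}

#' @export
print.ensemble_trajectories <- function(x, ...) {
  d <- dim(x$paths)
  cat(sprintf("<ensemble_trajectories> %d paths x %d times x %d states, dt = %g, seed = %d\n",
              d[1], d[2], d[3], x$dt, x$seed))
  invisible(x)
}

#' Cross-sectional ensemble moments at a time point
#'
#' Sample mean, unbiased covariance (divisor n - 1) and Pearson correlation
#' across paths at the grid time nearest `t`.
#'
#' @param traj an `ensemble_trajectories` object.
#' @param t requested time (snapped to the nearest grid point).
#' @return A list with `mean`, `cov`, `cor`, and the snapped `time`.
#' @export
ensemble_moments <- function(traj, t) {
  stopifnot(inherits(traj, "ensemble_trajectories"))
  if (t < min(traj$times) - traj$dt / 2 || t > max(traj$times) + traj$dt / 2)
    stop("time t outside the simulated range", call. = FALSE)
  if (dim(traj$paths)[1] < 2)
    stop("covariance undefined for fewer than 2 paths", call. = FALSE)
  i <- which.min(abs(traj$times - t))
  X <- traj$paths[, i, ]
  mu <- colMeans(X)
  S <- stats::cov(X)
  R <- if (all(diag(S) > 0)) stats::cov2cor(S) else
    matrix(NA_real_, nrow(S), ncol(S))  # degenerate at t = 0 (point mass)
  dimnames(S) <- dimnames(R) <- list(traj$state_names, traj$state_names)
  names(mu) <- traj$state_names
  list(mean = mu, cov = S, cor = R, time = traj$times[i])
}

#' Ensemble-mean trajectory
#'
#' @param traj an `ensemble_trajectories` object.
#' @return Matrix `n_t x 3` of path-averaged states at each time.
#' @export
ensemble_mean_trajectory <- function(traj) {
  stopifnot(inherits(traj, "ensemble_trajectories"))
  out <- apply(traj$paths, c(2, 3), mean)
  colnames(out) <- traj$state_names
  out
}

#' Tidy long-format view of an ensemble
#'
#' @param traj an `ensemble_trajectories` object.
#' @param thin keep every `thin`-th time point (the full grid can be large).
#' @return A data.frame with columns path, time, mu, b, eta.
#' @export
ensemble_as_data_frame <- function(traj, thin = 1L) {
  stopifnot(inherits(traj, "ensemble_trajectories"))
  keep <- seq(1, length(traj$times), by = thin)
  d <- dim(traj$paths)
  out <- do.call(rbind, lapply(keep, function(i) {
    data.frame(path = seq_len(d[1]), time = traj$times[i],
               mu = traj$paths[, i, 1], b = traj$paths[, i, 2],
               eta = traj$paths[, i, 3])
  }))
  rownames(out) <- NULL
  out
}
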