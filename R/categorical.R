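#' Construct the categorical master-equation analogue
#'
#' Builds the 3x3x3 categorical system whose steady state carries a Markov
#' blanket. The steady-state blanket marginal is
#' `softmax(kappa * log(1, 3, 1))` and the conditionals of the internal and
#' external states given the blanket are column-wise softmaxes of
#' `kappa * log` of a shared 3x3 table (columns indexed by the blanket
#' state). The joint factorizes as `s(mu|b) s(eta|b) s(b)`, which enforces
#' the blanket condition exactly. The flow over vec(s) decomposes into a
#' detailed-balance-preserving part `Gamma = (gamma/128) * (J - 27 I)` (J
#' the all-ones matrix) and a circulating part
#' `Q = (theta/512) * A \%x\% A \%x\% A` with
#' `A = [[0,-1,1],[1,0,-1],[-1,1,0]]`. The generator is
#' `L = (Gamma + Q) \%*\% Lambda`, `Lambda = diag(1 / vec(s_inf))`; its
#' off-diagonal entries are nonnegative iff `theta <= 4 * gamma`, which is
#' enforced.
#'
#' @param gamma rate of the dissipative (detailed-balance) flow component
#'   (> 0).
#' @param theta rate of the circulating (balance-breaking) component; must
#'   satisfy `theta <= 4 * gamma` for a valid rate matrix.
#' @param kappa inverse-temperature applied to the log steady-state tables
#'   (> 0).
#' @return An object of class `categorical_model` with the steady-state
#'   tables, the rate components `gamma_mat`, `q_mat`, the scaling
#'   `lambda_scale`, and the assembled `generator`.
#' @examples
#' cm <- categorical_model()
#' cm$s_b_inf  # (0.2, 0.6, 0.2)
#' @export
categorical_model <- function(gamma = 1, theta = 1, kappa = 1) {
  for (nm in c("gamma", "theta", "kappa")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a positive finite scalar", nm), call. = FALSE)
  }
  if (theta > 4 * gamma)
    stop(sprintf(paste("theta = %g exceeds 4 * gamma = %g: the transition-rate",
                       "matrix would acquire negative off-diagonal elements"),
                 theta, 4 * gamma), call. = FALSE)

  softmax_cols <- function(logw) {
    w <- exp(sweep(logw, 2, apply(logw, 2, max)))
    sweep(w, 2, colSums(w), "/")
  }
  s_b <- exp(kappa * log(c(1, 3, 1)))
  s_b <- s_b / sum(s_b)
  tab <- matrix(c(1, 3, 1,
                  3, 1, 1,
                  1, 1, 3), 3, 3, byrow = TRUE)  # rows: state, cols: b
  s_cond <- softmax_cols(kappa * log(tab))

  # joint s[mu, b, eta] = s(mu|b) s(eta|b) s(b)
  s_joint <- array(0, dim = c(3, 3, 3))
  for (b in 1:3) s_joint[, b, ] <- s_b[b] * outer(s_cond[, b], s_cond[, b])

  n <- 27L
  gamma_mat <- (gamma / 128) * (matrix(1, n, n) - n * diag(n))
  A <- matrix(c(0, -1, 1,
                1, 0, -1,
                -1, 1, 0), 3, 3, byrow = TRUE)
  q_mat <- (theta / 512) * kronecker(A, kronecker(A, A))
  v_inf <- as.numeric(s_joint)          # column-major: mu fastest, then b, eta
  lambda_scale <- diag(1 / v_inf)

  model <- structure(
    list(s_b_inf = s_b, s_mu_given_b = s_cond, s_eta_given_b = s_cond,
         s_joint_inf = s_joint, gamma_mat = gamma_mat, q_mat = q_mat,
         lambda_scale = lambda_scale, generator = NULL,
         gamma = gamma, theta = theta, kappa = kappa),
    class = "categorical_model"
  )
  model$generator <- build_generator(model)
  model
}

#' @export
print.categorical_model <- function(x, ...) {
  cat(sprintf("<categorical_model> 3x3x3 master-equation system, gamma = %g, theta = %g, kappa = %g\n",
              x$gamma, x$theta, x$kappa))
  cat("  steady-state blanket marginal:", signif(x$s_b_inf, 4), "\n")
  invisible(x)
}

#' Assemble the transition-rate generator
#'
#' `L = (Gamma + Q) \%*\% Lambda`, where `Lambda = diag(1 / vec(s_inf))`.
#' Because the rows and columns of both rate components sum to zero and
#' `Lambda` rescales columns by the reciprocal stationary probabilities,
#' `L \%*\% vec(s_inf) = 0` exactly and every column of L sums to zero
#' (probability conservation). Validity (nonnegative off-diagonals) is
#' checked and violations raise an error.
#'
#' @param model a [categorical_model()].
#' @return 27x27 transition-rate matrix.
#' @export
build_generator <- function(model) {
  stopifnot(inherits(model, "categorical_model"))
  Om <- model$gamma_mat + model$q_mat
  off <- Om - diag(diag(Om))
  if (min(off) < -1e-12)
    stop("invalid generator: negative off-diagonal rate component", call. = FALSE)
  Om %*% model$lambda_scale
}

#' Initial condition with an observed blanket state
#'
#' The categorical perturbation protocol: a distribution consistent with
#' steady state except that the blanket marginal is concentrated (one-hot)
#' on the most likely steady-state blanket state. The conditionals of mu
#' and eta given that blanket state equal their steady-state conditionals,
#' so the blanket-averaged conditional mutual information starts at zero.
#'
#' @param model a [categorical_model()].
#' @return 3x3x3 probability tensor (mu, b, eta) summing to 1.
#' @export
categorical_initial_condition <- function(model) {
  stopifnot(inherits(model, "categorical_model"))
  s_b <- model$s_b_inf
  top <- which(s_b == max(s_b))
  if (length(top) > 1L) {
    warning("tie in most likely blanket state; taking the lowest index",
            call. = FALSE)
    top <- top[1]
  }
  one_hot <- numeric(length(s_b))
  one_hot[top] <- 1
  s0 <- array(0, dim = dim(model$s_joint_inf))
  for (b in seq_along(s_b)) {
    if (one_hot[b] > 0)
      s0[, b, ] <- one_hot[b] * outer(model$s_mu_given_b[, b],
                                      model$s_eta_given_b[, b])
  }
  s0
}

#' Integrate the master equation
#'
#' Propagates `vec(ds/dt) = L vec(s)` over a uniform grid by repeated
#' application of the one-step matrix exponential `expm(L * dt)`, which
#' conserves total probability to round-off and keeps entries nonnegative
#' for a valid generator.
#'
#' @param model a [categorical_model()] (or a bare 27x27 generator matrix,
#'   in which case tensor dimensions (3,3,3) are assumed).
#' @param s0 initial probability tensor (mu, b, eta) on the simplex.
#' @param dt reporting step.
#' @param T horizon.
#' @return An object of class `categorical_trajectory`: `times` and
#'   `tensors` (array `3 x 3 x 3 x n_t`).
#' @export
integrate_master <- function(model, s0, dt = 1 / 32, T = 12) {
  L <- if (inherits(model, "categorical_model")) model$generator else unname(as.matrix(model))
  s0 <- as.array(s0)
  dims <- dim(s0)
  if (prod(dims) != nrow(L))
    stop("initial tensor does not match generator dimension", call. = FALSE)
  v0 <- as.numeric(s0)
  if (any(v0 < -1e-12) || abs(sum(v0) - 1) > 1e-8)
    stop("s0 must be a probability tensor on the simplex", call. = FALSE)
  n_steps <- round(T / dt)
  step <- as.matrix(Matrix::expm(L * dt))
  times <- seq(0, by = dt, length.out = n_steps + 1)
  tensors <- array(NA_real_, dim = c(dims, n_steps + 1))
  v <- v0
  tensors[, , , 1] <- s0
  for (s in seq_len(n_steps)) {
    v <- as.numeric(step %*% v)
    v <- pmax(v, 0)
    tensors[, , , s + 1] <- array(v, dim = dims)
  }
  structure(list(times = times, tensors = tensors),
            class = "categorical_trajectory")
}

#' @export
print.categorical_trajectory <- function(x, ...) {
  cat(sprintf("<categorical_trajectory> %d tensors over tau = [%g, %g]\n",
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Relaxation time constants of a categorical generator
#'
#' From the eigenvalues of L: for each eigenvalue with `Re(lambda) < -tol`,
#' returns `-1 / Re(lambda)`, sorted descending. The single zero mode
#' (probability conservation / the stationary distribution) is excluded.
#' The diagonal entries of L offer a cruder holding-time reading of the
#' same quantity and are available via `from = "diagonal"`.
#'
#' @param L generator matrix or a [categorical_model()].
#' @param tol zero-mode tolerance.
#' @param from `"eigenvalues"` (default) or `"diagonal"`.
#' @return Positive time constants, longest first.
#' @export
categorical_time_constants <- function(L, tol = 1e-10,
                                       from = c("eigenvalues", "diagonal")) {
  from <- match.arg(from)
  if (inherits(L, "categorical_model")) L <- L$generator
  L <- unname(as.matrix(L))
  if (from == "diagonal") {
    d <- diag(L)
    return(sort(-1 / d[d < -tol], decreasing = TRUE))
  }
  ev <- eigen(L, only.values = TRUE)$values
  re <- Re(ev)
  keep <- re < -tol
  out <- sort(-1 / re[keep], decreasing = TRUE)
  attr(out, "n_zero_modes") <- sum(!keep)
  out
}

#' Marginal distributions along a categorical trajectory
#'
#' @param traj a `categorical_trajectory`.
#' @return A data.frame (long format): time, state_group (mu/b/eta), level,
#'   probability.
#' @export
categorical_marginals <- function(traj) {
  stopifnot(inherits(traj, "categorical_trajectory"))
  nt <- length(traj$times)
  rows <- vector("list", nt)
  for (i in seq_len(nt)) {
    s <- traj$tensors[, , , i]
    rows[[i]] <- data.frame(
      time = traj$times[i],
      state_group = rep(c("mu", "b", "eta"), each = 3),
      level = rep(1:3, times = 3),
      probability = c(apply(s, 1, sum), apply(s, 2, sum), apply(s, 3, sum))
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tidy long-format view of a categorical trajectory
#'
#' @param traj a `categorical_trajectory`.
#' @return A data.frame: time, mu_state, b_state, eta_state, probability.
#' @export
categorical_as_data_frame <- function(traj) {
  stopifnot(inherits(traj, "categorical_trajectory"))
  grid <- expand.grid(mu_state = 1:3, b_state = 1:3, eta_state = 1:3)
  out <- do.call(rbind, lapply(seq_along(traj$times), function(i) {
    cbind(time = traj$times[i], grid,
          probability = as.numeric(traj$tensors[, , , i]))
  }))
  rownames(out) <- NULL
  out
}
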