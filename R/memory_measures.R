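#' Kullback-Leibler divergence between two multivariate Gaussians
#'
#' Closed form, in nats:
#' \deqn{D_{KL}[N(\alpha,A) \| N(\beta,B)] = \tfrac12\{\mathrm{tr}(B^{-1}A)
#'   + (\alpha-\beta)^\top B^{-1}(\alpha-\beta) - d + \ln\det B - \ln\det A\}.}
#'
#' @param mode_a,cov_a parameters of the first density.
#' @param mode_b,cov_b parameters of the second density.
#' @return Nonnegative scalar; zero iff the parameters are identical.
#' @examples
#' gaussian_kl(0, matrix(1), 1, matrix(1))  # 0.5
#' @export
gaussian_kl <- function(mode_a, cov_a, mode_b, cov_b) {
  a <- as.numeric(mode_a); b <- as.numeric(mode_b)
  A <- unname(as.matrix(cov_a)); B <- unname(as.matrix(cov_b))
  d <- length(a)
  if (length(b) != d || any(dim(A) != d) || any(dim(B) != d))
    stop("dimension mismatch between modes and covariances", call. = FALSE)
  cB <- tryCatch(chol(B), error = function(e)
    stop("second covariance is not positive-definite", call. = FALSE))
  cA <- tryCatch(chol(A), error = function(e)
    stop("first covariance is not positive-definite", call. = FALSE))
  Binv <- chol2inv(cB)
  delta <- a - b
  ldB <- 2 * sum(log(diag(cB)))
  ldA <- 2 * sum(log(diag(cA)))
  val <- 0.5 * (sum(Binv * A) + sum(delta * (Binv %*% delta)) - d + ldB - ldA)
  max(val, 0)
}

#' Blanket-conditioned covariance of internal and external states
#'
#' The covariance of p(mu, eta | b): the Schur complement of the blanket
#' block in the full covariance,
#' `Upsilon = Sigma[ie, ie] - Sigma[ie, b] solve(Sigma[b, b]) Sigma[b, ie]`
#' with `ie = (internal, external)`. Its off-diagonal block is zero exactly
#' when the Markov blanket condition holds.
#'
#' @param Sigma full symmetric positive-definite covariance.
#' @param partition a [blanket_partition()].
#' @return Matrix over the (internal, external) indices, with an
#'   `"blocks"` attribute giving the index ranges of the two groups.
#' @export
conditional_covariance <- function(Sigma, partition = blanket_partition()) {
  Sigma <- unname(as.matrix(Sigma))
  p <- partition
  ie <- c(p$internal, p$external)
  b <- p$blanket
  Sbb <- Sigma[b, b, drop = FALSE]
  Sbb_inv <- tryCatch(solve(Sbb), error = function(e)
    stop("blanket covariance block is singular", call. = FALSE))
  U <- Sigma[ie, ie, drop = FALSE] -
    Sigma[ie, b, drop = FALSE] %*% Sbb_inv %*% Sigma[b, ie, drop = FALSE]
  U <- (U + t(U)) / 2
  attr(U, "blocks") <- list(internal = seq_along(p$internal),
                            external = length(p$internal) + seq_along(p$external))
  U
}

#' Conditional mutual information between internal and external states
#'
#' I(mu; eta | b) for a Gaussian density with covariance `Sigma`, computed
#' from the blanket-conditioned covariance Upsilon as
#' `0.5 * (log det(U_ee) - log det(U_ee - U_em solve(U_mm) U_me))` (nats).
#' For scalar blocks this is `-0.5 * log(1 - rho^2)` with rho the
#' conditional correlation. Zero exactly when the blanket condition holds;
#' invariant under separate rescaling of the internal and external units.
#'
#' @param Sigma full covariance matrix.
#' @param partition a [blanket_partition()].
#' @return Nonnegative scalar (nats).
#' @export
conditional_mutual_information <- function(Sigma,
                                           partition = blanket_partition()) {
  U <- conditional_covariance(Sigma, partition)
  bl <- attr(U, "blocks")
  Umm <- U[bl$internal, bl$internal, drop = FALSE]
  Uee <- U[bl$external, bl$external, drop = FALSE]
  Uem <- U[bl$external, bl$internal, drop = FALSE]
  cond <- Uee - Uem %*% solve(Umm) %*% t(Uem)
  val <- 0.5 * (determinant_pd(Uee) - determinant_pd(cond))
  max(val, 0)
}

determinant_pd <- function(M) {
  ch <- tryCatch(chol(M), error = function(e)
    stop("matrix not positive-definite in conditional MI", call. = FALSE))
  2 * sum(log(diag(ch)))
}

#' Information length of a density trajectory
#'
#' Accumulates the path length travelled on the statistical manifold,
#' approximating each increment by `sqrt(2 * KL(p[j+1] || p[j]))` (the
#' leading, Fisher-metric, term of the divergence between infinitesimally
#' separated densities). For a Gaussian `density_trajectory` the length is
#' also computed for the blanket marginal alone; their difference is the
#' distance travelled that is not attributable to motion of the blanket
#' marginal.
#'
#' @param trajectory a `density_trajectory` or `categorical_trajectory`.
#' @param ... passed to methods.
#' @return A data.frame with columns `time`, `il_joint`, `il_blanket`,
#'   `il_excess` (cumulative, nondecreasing in time).
#' @export
information_length <- function(trajectory, ...) {
  UseMethod("information_length")
}

#' @rdname information_length
#' @param partition a [blanket_partition()] (continuous method).
#' @export
information_length.density_trajectory <- function(trajectory,
                                                  partition = blanket_partition(),
                                                  ...) {
  nt <- length(trajectory$times)
  b <- partition$blanket
  inc_joint <- inc_blanket <- numeric(nt - 1)
  for (j in seq_len(nt - 1)) {
    inc_joint[j] <- sqrt(2 * gaussian_kl(
      trajectory$modes[j + 1, ], trajectory$covariances[, , j + 1],
      trajectory$modes[j, ], trajectory$covariances[, , j]))
    inc_blanket[j] <- sqrt(2 * gaussian_kl(
      trajectory$modes[j + 1, b], trajectory$covariances[b, b, j + 1, drop = FALSE],
      trajectory$modes[j, b], trajectory$covariances[b, b, j, drop = FALSE]))
  }
  il_joint <- c(0, cumsum(inc_joint))
  il_blanket <- c(0, cumsum(inc_blanket))
  data.frame(time = trajectory$times, il_joint = il_joint,
             il_blanket = il_blanket, il_excess = il_joint - il_blanket)
}

#' @rdname information_length
#' @export
information_length.categorical_trajectory <- function(trajectory, ...) {
  nt <- length(trajectory$times)
  inc_joint <- inc_blanket <- numeric(nt - 1)
  # One-step divergence. When the older distribution has zero entries where
  # the newer is positive (the step off the simplex boundary from a one-hot
  # initial condition), the forward divergence is infinite even though the
  # continuum path length is finite; the reverse divergence, whose support
  # condition holds, is used for that step.
  step_div <- function(p_new, p_old) {
    if (any(p_new > 0 & p_old == 0)) categorical_kl(p_old, p_new)
    else categorical_kl(p_new, p_old)
  }
  for (j in seq_len(nt - 1)) {
    p_new <- trajectory$tensors[, , , j + 1]
    p_old <- trajectory$tensors[, , , j]
    inc_joint[j] <- sqrt(2 * step_div(as.numeric(p_new), as.numeric(p_old)))
    inc_blanket[j] <- sqrt(2 * step_div(apply(p_new, 2, sum),
                                        apply(p_old, 2, sum)))
  }
  il_joint <- c(0, cumsum(inc_joint))
  il_blanket <- c(0, cumsum(inc_blanket))
  data.frame(time = trajectory$times, il_joint = il_joint,
             il_blanket = il_blanket, il_excess = il_joint - il_blanket)
}

#' Generic information length from explicit one-step divergences
#'
#' @rdname information_length
#' @param kl function of (state_new, state_old) returning a one-step KL
#'   divergence; small negative values from round-off are clipped to zero
#'   with a warning.
#' @export
information_length.list <- function(trajectory, kl, ...) {
  nt <- length(trajectory)
  inc <- numeric(nt - 1)
  clipped <- FALSE
  for (j in seq_len(nt - 1)) {
    d <- kl(trajectory[[j + 1]], trajectory[[j]])
    if (d < 0) { clipped <- TRUE; d <- 0 }
    inc[j] <- sqrt(2 * d)
  }
  if (clipped)
    warning("negative one-step divergence clipped to zero", call. = FALSE)
  c(0, cumsum(inc))
}

#' Decay time constants from a Jacobian
#'
#' For each eigenvalue lambda of the (stable) Jacobian with |Re lambda|
#' above `tol`, returns `1 / |Re lambda|`, sorted descending: the time for
#' the associated eigenmode's amplitude to shrink by a factor e. Eigenvalues
#' with |Re lambda| <= tol (zero modes, e.g. probability conservation) are
#' excluded and reported via the `"n_zero_modes"` attribute.
#'
#' @param J square Jacobian matrix.
#' @param tol zero-mode tolerance on |Re lambda| (default 1e-10).
#' @return Numeric vector of positive time constants, longest first.
#' @examples
#' time_constants(diag(c(-2, -4)))  # 0.5 0.25
#' @export
time_constants <- function(J, tol = 1e-10) {
  J <- unname(as.matrix(J))
  ev <- eigen(J, only.values = TRUE)$values
  re <- Re(ev)
  keep <- abs(re) > tol
  out <- sort(1 / abs(re[keep]), decreasing = TRUE)
  attr(out, "n_zero_modes") <- sum(!keep)
  out
}

#' Kullback-Leibler divergence between categorical distributions
#'
#' `sum(p * log(p / q))` in nats with the convention `0 * log(0) = 0`.
#' Requires `q > 0` wherever `p > 0`.
#'
#' @param p,q probability vectors on the same simplex.
#' @return Nonnegative scalar (nats).
#' @export
categorical_kl <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != length(q))
    stop("p and q must have equal length", call. = FALSE)
  if (any(p < -1e-12) || any(q < -1e-12))
    stop("negative probabilities", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8)
    stop("p and q must each sum to 1", call. = FALSE)
  p <- pmax(p, 0); q <- pmax(q, 0)
  supp <- p > 0
  if (any(q[supp] == 0))
    stop("support violation: p > 0 where q = 0", call. = FALSE)
  max(sum(p[supp] * log(p[supp] / q[supp])), 0)
}

#' Blanket-averaged conditional mutual information, categorical case
#'
#' For a joint probability tensor `s[mu, b, eta]`, computes
#' `sum_b P(b) * I(mu; eta | b)`, each conditional mutual information taken
#' under the conditional joint `s(mu, eta | b)` in nats. Blanket states with
#' probability below `tol` contribute zero. Zero exactly when the tensor
#' factorizes as s(mu|b) s(eta|b) s(b).
#'
#' @param s 3-d array with dimensions (mu, b, eta), nonnegative, summing
#'   to 1.
#' @param tol blanket states with marginal probability below this are
#'   skipped.
#' @return Nonnegative scalar (nats).
#' @export
categorical_cmi <- function(s, tol = 1e-12) {
  s <- as.array(s)
  if (length(dim(s)) != 3L)
    stop("s must be a 3-d probability tensor (mu, b, eta)", call. = FALSE)
  if (any(s < -1e-12))
    stop("negative entries in probability tensor", call. = FALSE)
  s <- pmax(s, 0)
  if (abs(sum(s) - 1) > 1e-6)
    stop("probability tensor must sum to 1", call. = FALSE)
  p_b <- apply(s, 2, sum)
  total <- 0
  for (j in seq_along(p_b)) {
    if (p_b[j] < tol) next
    joint <- s[, j, ] / p_b[j]          # s(mu, eta | b = j)
    p_mu <- rowSums(joint)
    p_eta <- colSums(joint)
    supp <- joint > 0
    ref <- outer(p_mu, p_eta)
    mi <- sum(joint[supp] * log(joint[supp] / ref[supp]))
    total <- total + p_b[j] * max(mi, 0)
  }
  total
}

#' Memory measure series along a continuous relaxation
#'
#' Convenience wrapper: given a model and a density trajectory, computes the
#' time series of blanket-conditioned mutual information, the
#' internal-external precision entry, and the three information lengths,
#' plus the covariance-flow time constants.
#'
#' @param m a [gaussian_model()].
#' @param traj a `density_trajectory`.
#' @return A list with `measures` (data.frame: time, cmi, phi_mu_eta,
#'   il_joint, il_blanket, il_excess) and `time_constants`.
#' @export
measure_series <- function(m, traj) {
  stopifnot(inherits(m, "gaussian_model"), inherits(traj, "density_trajectory"))
  p <- m$partition
  nt <- length(traj$times)
  cmi <- numeric(nt)
  phi_me <- numeric(nt)
  for (i in seq_len(nt)) {
    S <- traj$covariances[, , i]
    cmi[i] <- conditional_mutual_information(S, p)
    Phi <- solve(S)
    phi_me[i] <- Phi[p$internal[1], p$external[1]]
  }
  il <- information_length(traj, partition = p)
  list(
    measures = data.frame(time = traj$times, cmi = cmi, phi_mu_eta = phi_me,
                          il_joint = il$il_joint, il_blanket = il$il_blanket,
                          il_excess = il$il_excess),
    time_constants = time_constants(covariance_jacobian(m))
  )
}
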