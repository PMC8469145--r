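#' Three-way state partition for a Markov blanket
#'
#' Describes which indices of the state vector are internal, blanket and
#' external. A Markov blanket holds at steady state when internal and
#' external states are conditionally independent given the blanket, i.e.
#' p(mu, eta | b) = p(mu | b) p(eta | b).
#'
#' @param internal,blanket,external integer index vectors over the state
#'   dimension. Must be disjoint, nonempty, and jointly cover `1:n`.
#' @return An object of class `blanket_partition`.
#' @examples
#' blanket_partition()  # the canonical (mu, b, eta) = (1, 2, 3) ordering
#' @export
blanket_partition <- function(internal = 1L, blanket = 2L, external = 3L) {
  internal <- as.integer(internal)
  blanket <- as.integer(blanket)
  external <- as.integer(external)
  idx <- c(internal, blanket, external)
  if (any(lengths(list(internal, blanket, external)) == 0L))
    stop("each partition cell must be nonempty", call. = FALSE)
  if (anyDuplicated(idx))
    stop("partition cells must be disjoint", call. = FALSE)
  if (!setequal(idx, seq_along(idx)))
    stop("partition must cover state indices 1..n exactly", call. = FALSE)
  structure(
    list(internal = internal, blanket = blanket, external = external,
         n = length(idx)),
    class = "blanket_partition"
  )
}

#' @export
print.blanket_partition <- function(x, ...) {
  cat("<blanket_partition> internal:", x$internal,
      "| blanket:", x$blanket, "| external:", x$external, "\n")
  invisible(x)
}

#' Construct the three-state Ornstein-Uhlenbeck model
#'
#' Builds the quadratic-potential (Ornstein-Uhlenbeck) system over states
#' (mu, b, eta) whose non-equilibrium steady state carries a Markov blanket.
#' The steady-state density is N(theta_mode, solve(hessian)) with Hessian
#' \deqn{\Pi = \begin{pmatrix} 2\kappa & \sqrt\kappa & 0 \\
#'   \sqrt\kappa & 2 & \sqrt\kappa \\ 0 & \sqrt\kappa & 2\kappa
#'   \end{pmatrix}}
#' whose zero (mu, eta) entry enforces the blanket condition. The flow
#' decomposes into a dissipative part with diffusion
#' `Gamma = diag(gamma, 1, gamma) / 4` and a solenoidal part
#' `Q = theta * [[0,-1,0],[1,0,-1],[0,1,0]]` circulating along the contours
#' of the potential. This parameterization has the property that the
#' stationary marginal variances of mu and eta scale as 3/(4 kappa) while
#' the conditional blanket variances stay fixed at 2/3.
#'
#' @param gamma rate constant of the dissipative flow on the internal and
#'   external channels (dimensionless rate; > 0).
#' @param theta rate constant of the solenoidal flow (1/time; > 0).
#' @param kappa steady-state precision scale of the internal/external
#'   marginals (inverse variance; > 0).
#' @return An object of class `gaussian_model` with elements `theta_mode`,
#'   `hessian`, `diffusion`, `solenoidal`, the three scalars, and the
#'   `partition`.
#' @examples
#' m <- gaussian_model()
#' stationary_covariance(m)
#' @export
gaussian_model <- function(gamma = 1, theta = 1, kappa = 1) {
  for (nm in c("gamma", "theta", "kappa")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a positive finite scalar", nm), call. = FALSE)
  }
  sk <- sqrt(kappa)
  hessian <- matrix(c(2 * kappa, sk, 0,
                      sk, 2, sk,
                      0, sk, 2 * kappa), 3, 3, byrow = TRUE)
  diffusion <- diag(c(gamma, 1, gamma)) / 4
  solenoidal <- theta * matrix(c(0, -1, 0,
                                 1, 0, -1,
                                 0, 1, 0), 3, 3, byrow = TRUE)
  m <- new_gaussian_model(
    theta_mode = c(0, 0, 0), hessian = hessian, diffusion = diffusion,
    solenoidal = solenoidal, gamma = gamma, theta = theta, kappa = kappa,
    partition = blanket_partition()
  )
  assert_blanket_structure(m)
  m
}

#' Assemble a Gaussian blanket model from explicit matrices
#'
#' Low-level constructor for systems outside the standard parameterization.
#' All structural invariants are checked via [assert_blanket_structure()].
#'
#' @param theta_mode mode of the steady-state density (state units).
#' @param hessian symmetric positive-definite Hessian of the potential, with
#'   zero internal-external block.
#' @param diffusion symmetric positive-semidefinite diffusion matrix (half
#'   the fluctuation covariance).
#' @param solenoidal antisymmetric solenoidal flow matrix.
#' @param partition a [blanket_partition()].
#' @param gamma,theta,kappa optional scalar tags carried along for
#'   provenance; `NA` when the model does not arise from the standard
#'   parameterization.
#' @return A `gaussian_model`.
#' @export
as_gaussian_model <- function(theta_mode, hessian, diffusion, solenoidal,
                              partition = blanket_partition(),
                              gamma = NA_real_, theta = NA_real_,
                              kappa = NA_real_) {
  m <- new_gaussian_model(theta_mode, hessian, diffusion, solenoidal,
                          gamma, theta, kappa, partition)
  assert_blanket_structure(m)
  m
}

new_gaussian_model <- function(theta_mode, hessian, diffusion, solenoidal,
                               gamma, theta, kappa, partition) {
  structure(
    list(theta_mode = as.numeric(theta_mode),
         hessian = unname(as.matrix(hessian)),
         diffusion = unname(as.matrix(diffusion)),
         solenoidal = unname(as.matrix(solenoidal)),
         gamma = gamma, theta = theta, kappa = kappa,
         partition = partition),
    class = "gaussian_model"
  )
}

#' @export
print.gaussian_model <- function(x, ...) {
  cat("<gaussian_model> Ornstein-Uhlenbeck system with Markov blanket at NESS\n")
  if (is.finite(x$gamma))
    cat(sprintf("  gamma = %g, theta = %g, kappa = %g\n",
                x$gamma, x$theta, x$kappa))
  cat("  Hessian Pi:\n")
  print(x$hessian)
  invisible(x)
}

#' Stationary covariance of the model
#'
#' The steady-state density is proportional to exp(-potential), so its
#' covariance is the inverse Hessian. For the standard parameterization this
#' satisfies `Sigma[1,1] = Sigma[3,3] = 3/(4*kappa)`, `Sigma[2,2] = 1`, and
#' conditional blanket variances of 2/3 for all kappa.
#'
#' @param m a `gaussian_model`.
#' @return Symmetric positive-definite 3x3 covariance matrix.
#' @export
stationary_covariance <- function(m) {
  stopifnot(inherits(m, "gaussian_model"))
  S <- tryCatch(solve(m$hessian),
                error = function(e) stop("Hessian is singular: ",
                                         conditionMessage(e), call. = FALSE))
  (S + t(S)) / 2
}

#' Deterministic drift of the stochastic differential equation
#'
#' The flow is `f(x) = -(Gamma - Q) Pi (x - theta_mode)`: gradient descent
#' on the potential tempered by the diffusion, plus a solenoidal orbit along
#' its contours. The mode `theta_mode` is the unique fixed point.
#'
#' @param m a `gaussian_model`.
#' @param x numeric state vector of the model's dimension.
#' @return Velocity vector of the same dimension.
#' @export
drift <- function(m, x) {
  stopifnot(inherits(m, "gaussian_model"))
  x <- as.numeric(x)
  if (length(x) != nrow(m$hessian))
    stop("state vector has wrong dimension", call. = FALSE)
  as.numeric(-(drift_matrix(m) %*% (x - m$theta_mode)))
}

# A = (Gamma - Q) Pi, so that f(x) = -A (x - theta_mode)
drift_matrix <- function(m) {
  (m$diffusion - m$solenoidal) %*% m$hessian
}

#' Validate the structural invariants of a Gaussian blanket model
#'
#' Checks that the Hessian is symmetric positive-definite with a zero
#' internal-external block (the blanket condition), that the solenoidal
#' matrix is antisymmetric, and that the diffusion matrix is symmetric
#' positive-semidefinite. Violations raise a condition of class
#' `blanketmem_invariant_error` naming the failed invariant.
#'
#' @param m a `gaussian_model`.
#' @param tol numeric tolerance for the structural checks.
#' @return Invisibly, a named logical vector of the checks (all `TRUE` on
#'   success).
#' @export
assert_blanket_structure <- function(m, tol = 1e-10) {
  stopifnot(inherits(m, "gaussian_model"))
  p <- m$partition
  Pi <- m$hessian
  fail <- function(which, msg) {
    stop(structure(
      class = c("blanketmem_invariant_error", "error", "condition"),
      list(message = sprintf("invariant '%s' violated: %s", which, msg),
           call = sys.call(-1), invariant = which)))
  }
  if (max(abs(Pi - t(Pi))) > tol)
    fail("hessian_symmetric", "Pi != t(Pi)")
  if (max(abs(Pi[p$internal, p$external, drop = FALSE])) > tol)
    fail("blanket_condition", "Pi[internal, external] != 0")
  ev <- eigen(Pi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= tol)
    fail("hessian_positive_definite",
         sprintf("min eigenvalue %.3g <= 0", min(ev)))
  Q <- m$solenoidal
  if (max(abs(Q + t(Q))) > tol)
    fail("solenoidal_antisymmetric", "Q != -t(Q)")
  G <- m$diffusion
  if (max(abs(G - t(G))) > tol)
    fail("diffusion_symmetric", "Gamma != t(Gamma)")
  evg <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(evg) < -tol)
    fail("diffusion_positive_semidefinite",
         sprintf("min eigenvalue %.3g < 0", min(evg)))
  invisible(c(hessian_symmetric = TRUE, blanket_condition = TRUE,
              hessian_positive_definite = TRUE,
              solenoidal_antisymmetric = TRUE,
              diffusion_symmetric = TRUE,
              diffusion_positive_semidefinite = TRUE))
}
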