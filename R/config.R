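#' Serialize a model to a flat key-value config
#'
#' Writes the scalar parameterization (gamma, theta, kappa) when the model
#' was built from it, or the explicit matrices otherwise, as flat YAML.
#'
#' @param m a [gaussian_model()].
#' @param path file path to write; `NULL` returns the config list.
#' @return Invisibly (or visibly when `path` is `NULL`), the config list.
#' @export
write_model_config <- function(m, path = NULL) {
  stopifnot(inherits(m, "gaussian_model"))
  cfg <- if (is.finite(m$gamma)) {
    list(gamma = m$gamma, theta = m$theta, kappa = m$kappa)
  } else {
    list(theta_mode = as.numeric(m$theta_mode),
         hessian = as.numeric(m$hessian),
         diffusion = as.numeric(m$diffusion),
         solenoidal = as.numeric(m$solenoidal),
         dim = nrow(m$hessian))
  }
  if (is.null(path)) return(cfg)
  yaml::write_yaml(cfg, path)
  invisible(cfg)
}

#' Read a model from a flat key-value config
#'
#' Accepts either the scalar form (keys gamma, theta, kappa) or the explicit
#' matrix form (theta_mode, hessian, diffusion, solenoidal as column-major
#' flattened vectors plus dim).
#'
#' @param path YAML file path, or a list as produced by
#'   [write_model_config()].
#' @return A [gaussian_model()].
#' @export
read_model_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  if (!is.null(cfg$gamma) && is.null(cfg$hessian)) {
    gaussian_model(gamma = cfg$gamma, theta = cfg$theta, kappa = cfg$kappa)
  } else {
    n <- cfg$dim
    as_gaussian_model(
      theta_mode = cfg$theta_mode,
      hessian = matrix(cfg$hessian, n, n),
      diffusion = matrix(cfg$diffusion, n, n),
      solenoidal = matrix(cfg$solenoidal, n, n)
    )
  }
}
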