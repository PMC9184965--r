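#' Assemble a landscape model
#'
#' A landscape model bundles a potential family \eqn{F(x;\theta)}, a
#' Riemannian metric \eqn{G(x)}, a parameter vector \eqn{\theta} and a
#' noise amplitude \eqn{\sigma}. Its deterministic dynamics are
#' \eqn{\dot x = -G(x)^{-1}\nabla F(x;\theta)}; the stochastic version adds
#' additive isotropic white noise of amplitude \eqn{\sigma}.
#'
#' @param family a `potential_family`
#' @param theta parameter vector (length `family$n_params`)
#' @param metric a `riemannian_metric`; identity by default
#' @param sigma noise amplitude (dimensionless, >= 0)
#' @return an object of class `landscape_model`
#' @export
landscape_model <- function(family, theta = numeric(family$n_params),
                            metric = identity_metric(2L), sigma = 0) {
  stopifnot(inherits(family, "potential_family"),
            inherits(metric, "riemannian_metric"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    stop("sigma must be a single non-negative number", call. = FALSE)
  }
  theta <- check_theta(family, theta)
  structure(list(family = family, metric = metric, theta = theta,
                 sigma = sigma),
            class = "landscape_model")
}

#' @export
print.landscape_model <- function(x, ...) {
  cat(sprintf("<landscape_model: family '%s', theta = (%s), sigma = %g, %s metric>\n",
              x$family$name, paste(signif(x$theta, 4), collapse = ", "),
              x$sigma,
              if (x$metric$is_constant) "constant" else "position-dependent"))
  invisible(x)
}

#' Piecewise-linear signal path through parameter space
#'
#' Signals are modelled as time-dependent unfolding parameters: a path
#' \eqn{\theta(t)} interpolated linearly between knots. Outside `t_grid`
#' the endpoint values are held constant.
#'
#' @param t_grid strictly increasing knot times
#' @param thetas matrix with `length(t_grid)` rows (one parameter vector
#'   per knot); a vector is accepted for a one-parameter family
#' @return an object of class `signal_path`
#' @export
signal_path <- function(t_grid, thetas) {
  t_grid <- as.numeric(t_grid)
  if (any(diff(t_grid) <= 0)) {
    stop("t_grid must be strictly increasing", call. = FALSE)
  }
  if (!is.matrix(thetas)) thetas <- matrix(thetas, nrow = length(t_grid))
  if (nrow(thetas) != length(t_grid)) {
    stop("thetas must have one row per knot time", call. = FALSE)
  }
  structure(list(t_grid = t_grid, thetas = thetas,
                 n_params = ncol(thetas)),
            class = "signal_path")
}

#' Constant (frozen) signal path
#' @param theta parameter vector
#' @param t_end end of the nominal time range
#' @export
constant_path <- function(theta, t_end = 1) {
  signal_path(c(0, t_end), rbind(theta, theta))
}

#' Evaluate a signal path at time(s) `t`
#' @param path a `signal_path`
#' @param t time or vector of times
#' @return parameter vector (or matrix, one row per time)
#' @export
theta_at <- function(path, t) {
  stopifnot(inherits(path, "signal_path"))
  out <- vapply(seq_len(path$n_params), function(j) {
    stats::approx(path$t_grid, path$thetas[, j], xout = t, rule = 2)$y
  }, numeric(length(t)))
  if (length(t) == 1L) as.numeric(out) else matrix(out, nrow = length(t))
}

# Internal: resolve a theta-or-path argument to a path.
as_signal_path <- function(theta_or_path, t_end) {
  if (inherits(theta_or_path, "signal_path")) theta_or_path
  else constant_path(theta_or_path, t_end)
}
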