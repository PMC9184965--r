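#' Construct a Riemannian metric
#'
#' A Riemannian metric assigns to every phase point \eqn{x} a symmetric
#' positive definite (SPD) matrix \eqn{G(x)}. Together with a potential
#' \eqn{F} it defines the gradient dynamics \eqn{\dot x = -G^{-1}\nabla F}.
#' Changing \eqn{G} leaves the rest points and their Morse indices
#' untouched but can reroute the unstable manifolds of the saddles, i.e.
#' redirect the escape routes cells follow between attractors.
#'
#' @param G either a constant SPD matrix or a function `x -> matrix`
#' @return an object of class `riemannian_metric` with fields `evaluate`
#'   and `is_constant`
#' @export
#' @examples
#' riemannian_metric(matrix(c(1, -0.6, -0.6, 1), 2, 2))
riemannian_metric <- function(G) {
  if (is.matrix(G)) {
    check_spd(G)
    Gc <- G
    Gi <- solve(G)
    m <- structure(
      list(evaluate = function(x) Gc, inv = function(x) Gi,
           is_constant = TRUE, matrix = Gc),
      class = "riemannian_metric")
  } else if (is.function(G)) {
    m <- structure(
      list(evaluate = function(x) {
        M <- G(x)
        check_spd(M)
        M
      },
      inv = function(x) solve(G(x)),
      is_constant = FALSE, matrix = NULL),
      class = "riemannian_metric")
  } else {
    stop("G must be a matrix or a function of the phase point", call. = FALSE)
  }
  m
}

#' The identity (standard Euclidean) metric
#' @param dim phase-space dimension
#' @return a constant `riemannian_metric`
#' @export
identity_metric <- function(dim = 2L) riemannian_metric(diag(dim))

check_spd <- function(M, tol = 1e-10) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) {
    stop("metric must be a square matrix", call. = FALSE)
  }
  if (max(abs(M - t(M))) > tol) {
    stop("metric matrix is not symmetric", call. = FALSE)
  }
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf(
      "metric is not positive definite (smallest eigenvalue %.6g)", min(ev)),
      call. = FALSE)
  }
  invisible(TRUE)
}

#' Evaluate a metric at a phase point
#'
#' @param metric a `riemannian_metric`
#' @param x phase point
#' @return the SPD matrix \eqn{G(x)}; an error if the evaluated matrix is
#'   not symmetric positive definite
#' @export
eval_metric <- function(metric, x) {
  stopifnot(inherits(metric, "riemannian_metric"))
  M <- metric$evaluate(x)
  check_spd(M)
  M
}
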