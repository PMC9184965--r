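# Internal: coerce a phase point (length-2 vector) or a set of points
# (n x 2 matrix) to an n x 2 matrix.
as_points <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 2L) stop("phase points must have 2 columns", call. = FALSE)
    x
  } else {
    if (length(x) != 2L) stop("phase point must have length 2", call. = FALSE)
    matrix(as.numeric(x), nrow = 1L)
  }
}

new_potential_family <- function(name, n_params, f, grad, hess,
                                 domain_box, param_box, hess_v = NULL) {
  structure(
    list(
      name = name,
      dim = 2L,
      n_params = as.integer(n_params),
      f = f, grad = grad, hess = hess,
      # optional vectorised Hessian: X (n x 2) -> n x 3 (hxx, hxy, hyy)
      hess_v = hess_v,
      domain_box = domain_box,
      param_box = param_box
    ),
    class = "potential_family"
  )
}

#' @export
print.potential_family <- function(x, ...) {
  cat(sprintf("<potential_family '%s': dim %d, %d unfolding parameter(s)>\n",
              x$name, x$dim, x$n_params))
  invisible(x)
}

check_theta <- function(family, theta) {
  theta <- as.numeric(theta)
  if (length(theta) != family$n_params) {
    stop(sprintf("family '%s' expects %d parameter(s), got %d",
                 family$name, family$n_params, length(theta)), call. = FALSE)
  }
  theta
}

# The compactified elliptic umbilic potential and its exact derivatives.
# F(x, y; a, b) = x^3 - 2 x y^2 - 0.4 x^2 + a x + b y + (x^4 + y^4) / 4
eu_f <- function(x, y, a, b) {
  x^3 - 2 * x * y^2 - 0.4 * x^2 + a * x + b * y + (x^4 + y^4) / 4
}
eu_gx <- function(x, y, a, b) 3 * x^2 - 2 * y^2 - 0.8 * x + a + x^3
eu_gy <- function(x, y, a, b) -4 * x * y + b + y^3
eu_hess <- function(x, y) {
  matrix(c(6 * x - 0.8 + 3 * x^2, -4 * y,
           -4 * y, -4 * x + 3 * y^2), 2L, 2L)
}

#' Construct a potential family from the built-in catalogue
#'
#' Returns one of the canonical two-parameter landscape families used
#' throughout the package. All catalogue families are polynomial in the phase
#' variables \eqn{(x, y)} with quartic-or-higher confining terms, so the
#' potential grows to \eqn{+\infty} in every direction and all trajectories
#' stay bounded. Derivatives are analytic.
#'
#' Available families:
#' \describe{
#'   \item{`elliptic_umbilic`}{The compactified elliptic umbilic,
#'     \eqn{F = x^3 - 2xy^2 - 0.4x^2 + ax + by + (x^4+y^4)/4}. Supports up
#'     to three attractors and contains both fold and heteroclinic-flip
#'     bifurcations; the workhorse binary-flip family.}
#'   \item{`box2_example`}{The elliptic umbilic frozen at \eqn{(a, b) =
#'     (-3, -1)}; a fixed tristable landscape with no free parameters, used
#'     to demonstrate that the Riemannian metric (not the potential alone)
#'     determines where unstable manifolds go.}
#'   \item{`cusp1d`}{The classical cusp unfolding
#'     \eqn{F = x^4/4 + a x^2/2 + b x + y^2/2}, embedded in 2D by a
#'     quadratic transverse term. Bistable inside the cusp region.}
#'   \item{`dual_cusp1d`}{A sextic normal form
#'     \eqn{F = x^6/6 - x^4/4 + a x^2/2 + b x + y^2/2} whose bifurcation set
#'     contains a dual cusp; the inside of the dual cusp is tristable
#'     (binary-choice landscape).}
#'   \item{`flip_with_cusp`}{The elliptic umbilic restricted to a small
#'     parameter box near the origin that contains one fold curve, a cusp,
#'     and a flip-curve termination.}
#' }
#'
#' @param name one of `"elliptic_umbilic"`, `"box2_example"`, `"cusp1d"`,
#'   `"dual_cusp1d"`, `"flip_with_cusp"`.
#' @param options optional list; `domain_box` overrides the default
#'   axis-aligned phase-space search box (list with `lower`, `upper`).
#' @return an object of class `potential_family` with fields `name`, `dim`,
#'   `n_params`, `f`, `grad`, `hess`, `domain_box`, `param_box`.
#' @export
#' @examples
#' fam <- make_family("cusp1d")
#' eval_potential(fam, c(1, 0), c(-1, 0))
make_family <- function(name, options = list()) {
  catalogue <- c("elliptic_umbilic", "box2_example", "cusp1d",
                 "dual_cusp1d", "flip_with_cusp")
  if (!is.character(name) || length(name) != 1L || !(name %in% catalogue)) {
    stop(sprintf("unknown family '%s'; valid names are: %s",
                 as.character(name)[1], paste(catalogue, collapse = ", ")),
         call. = FALSE)
  }

  box <- function(lo, hi) list(lower = c(lo, lo), upper = c(hi, hi))

  fam <- switch(
    name,
    elliptic_umbilic = new_potential_family(
      name, 2L,
      f    = function(x, theta) {
        p <- as_points(x); eu_f(p[, 1], p[, 2], theta[1], theta[2])
      },
      grad = function(x, theta) {
        p <- as_points(x)
        g <- cbind(eu_gx(p[, 1], p[, 2], theta[1], theta[2]),
                   eu_gy(p[, 1], p[, 2], theta[1], theta[2]))
        if (nrow(g) == 1L) drop(g) else g
      },
      hess = function(x, theta) {
        p <- as_points(x); eu_hess(p[1, 1], p[1, 2])
      },
      domain_box = box(-6, 6),
      param_box  = list(lower = c(-3, -3), upper = c(3, 3)),
      hess_v = function(X, theta) {
        cbind(6 * X[, 1] - 0.8 + 3 * X[, 1]^2, -4 * X[, 2],
              -4 * X[, 1] + 3 * X[, 2]^2)
      }
    ),
    box2_example = new_potential_family(
      name, 0L,
      f    = function(x, theta = numeric(0)) {
        p <- as_points(x); eu_f(p[, 1], p[, 2], -3, -1)
      },
      grad = function(x, theta = numeric(0)) {
        p <- as_points(x)
        g <- cbind(eu_gx(p[, 1], p[, 2], -3, -1),
                   eu_gy(p[, 1], p[, 2], -3, -1))
        if (nrow(g) == 1L) drop(g) else g
      },
      hess = function(x, theta = numeric(0)) {
        p <- as_points(x); eu_hess(p[1, 1], p[1, 2])
      },
      domain_box = box(-6, 6),
      param_box  = list(lower = numeric(0), upper = numeric(0)),
      hess_v = function(X, theta) {
        cbind(6 * X[, 1] - 0.8 + 3 * X[, 1]^2, -4 * X[, 2],
              -4 * X[, 1] + 3 * X[, 2]^2)
      }
    ),
    cusp1d = new_potential_family(
      name, 2L,
      f    = function(x, theta) {
        p <- as_points(x)
        p[, 1]^4 / 4 + theta[1] * p[, 1]^2 / 2 + theta[2] * p[, 1] +
          p[, 2]^2 / 2
      },
      grad = function(x, theta) {
        p <- as_points(x)
        g <- cbind(p[, 1]^3 + theta[1] * p[, 1] + theta[2], p[, 2])
        if (nrow(g) == 1L) drop(g) else g
      },
      hess = function(x, theta) {
        p <- as_points(x)
        matrix(c(3 * p[1, 1]^2 + theta[1], 0, 0, 1), 2L, 2L)
      },
      domain_box = box(-4, 4),
      param_box  = list(lower = c(-3, -3), upper = c(3, 3)),
      hess_v = function(X, theta) {
        cbind(3 * X[, 1]^2 + theta[1], rep(0, nrow(X)), rep(1, nrow(X)))
      }
    ),
    dual_cusp1d = new_potential_family(
      name, 2L,
      f    = function(x, theta) {
        p <- as_points(x)
        p[, 1]^6 / 6 - p[, 1]^4 / 4 + theta[1] * p[, 1]^2 / 2 +
          theta[2] * p[, 1] + p[, 2]^2 / 2
      },
      grad = function(x, theta) {
        p <- as_points(x)
        g <- cbind(p[, 1]^5 - p[, 1]^3 + theta[1] * p[, 1] + theta[2],
                   p[, 2])
        if (nrow(g) == 1L) drop(g) else g
      },
      hess = function(x, theta) {
        p <- as_points(x)
        matrix(c(5 * p[1, 1]^4 - 3 * p[1, 1]^2 + theta[1], 0, 0, 1), 2L, 2L)
      },
      domain_box = box(-3, 3),
      param_box  = list(lower = c(-3, -3), upper = c(3, 3)),
      hess_v = function(X, theta) {
        cbind(5 * X[, 1]^4 - 3 * X[, 1]^2 + theta[1],
              rep(0, nrow(X)), rep(1, nrow(X)))
      }
    ),
    flip_with_cusp = {
      base <- make_family("elliptic_umbilic")
      base$name <- "flip_with_cusp"
      # Sub-box of the elliptic umbilic parameter plane holding one fold
      # curve, one cusp and a flip-curve termination (near the organizing
      # centre at the origin).
      base$param_box <- list(lower = c(-0.6, -0.25), upper = c(0.25, 0.25))
      base
    }
  )

  # id of the compiled simulation core for this family's polynomial
  fam$cpp_id <- switch(name, elliptic_umbilic = 1L, box2_example = 1L,
                       flip_with_cusp = 1L, cusp1d = 2L, dual_cusp1d = 3L)
  if (!is.null(options$domain_box)) fam$domain_box <- options$domain_box
  fam
}

#' Evaluate a catalogue potential
#'
#' @param family a `potential_family`
#' @param x phase point (length-2 vector) or n x 2 matrix of points
#' @param theta unfolding parameter vector (length `family$n_params`)
#' @return scalar (or vector over rows of `x`)
#' @export
eval_potential <- function(family, x, theta = numeric(0)) {
  stopifnot(inherits(family, "potential_family"))
  family$f(x, check_theta(family, theta))
}

#' Evaluate the analytic gradient \eqn{\nabla F(x; \theta)}
#' @inheritParams eval_potential
#' @return length-2 vector (or n x 2 matrix)
#' @export
eval_gradient <- function(family, x, theta = numeric(0)) {
  stopifnot(inherits(family, "potential_family"))
  family$grad(x, check_theta(family, theta))
}

#' Evaluate the analytic Hessian of \eqn{F}
#' @inheritParams eval_potential
#' @return symmetric 2 x 2 matrix
#' @export
eval_hessian <- function(family, x, theta = numeric(0)) {
  stopifnot(inherits(family, "potential_family"))
  family$hess(x, check_theta(family, theta))
}

# Order-2 central finite differences, used as a fallback for user-supplied
# families and as an internal cross-check.
fd_gradient <- function(f, x, theta, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e, theta) - f(x - e, theta)) / (2 * h)
  }, numeric(1))
}

fd_hessian <- function(f, x, theta, h = 1e-4) {
  n <- length(x)
  H <- matrix(0, n, n)
  f0 <- f(x, theta)
  for (i in seq_len(n)) {
    ei <- numeric(n); ei[i] <- h
    H[i, i] <- (f(x + ei, theta) - 2 * f0 + f(x - ei, theta)) / h^2
    if (i < n) for (j in (i + 1):n) {
      ej <- numeric(n); ej[j] <- h
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej, theta) - f(x + ei - ej, theta) -
           f(x - ei + ej, theta) + f(x - ei - ej, theta)) / (4 * h^2)
    }
  }
  H
}

#' Build a custom potential family
#'
#' Wraps user-supplied functions into a `potential_family`. If `grad` or
#' `hess` are omitted they fall back to order-2 central finite differences
#' (step 1e-5 for the gradient, 1e-4 for the Hessian).
#'
#' @param name identifier
#' @param f function `(x, theta) -> scalar`
#' @param grad,hess optional analytic derivatives
#' @param n_params number of unfolding parameters
#' @param domain_box list with `lower`, `upper` (length-2 each)
#' @param param_box optional parameter box in the same format
#' @return a `potential_family`
#' @export
potential_family <- function(name, f, grad = NULL, hess = NULL,
                             n_params = 2L,
                             domain_box = list(lower = c(-5, -5),
                                               upper = c(5, 5)),
                             param_box = list(lower = rep(-3, n_params),
                                              upper = rep(3, n_params))) {
  if (is.null(grad)) {
    grad <- function(x, theta) {
      p <- as_points(x)
      g <- t(apply(p, 1L, function(row) fd_gradient(f, row, theta)))
      if (nrow(p) == 1L) drop(g) else g
    }
  }
  if (is.null(hess)) {
    hess <- function(x, theta) {
      p <- as_points(x)
      fd_hessian(f, p[1, ], theta)
    }
  }
  new_potential_family(name, n_params, f, grad, hess, domain_box, param_box)
}
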