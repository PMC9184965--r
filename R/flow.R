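#' Metric gradient vector field
#'
#' Solves \eqn{G(x) v = -\nabla F(x; \theta)} for the velocity `v`. With
#' the identity metric this is plain steepest descent; with a non-trivial
#' metric the flow still descends the potential but crosses its level sets
#' at non-right angles.
#'
#' @param model a `landscape_model`
#' @param x phase point
#' @param theta parameters (defaults to the model's)
#' @return velocity vector
#' @export
vector_field <- function(model, x, theta = model$theta) {
  g <- eval_gradient(model$family, x, theta)
  G <- eval_metric(model$metric, x)
  -solve(G, g)
}

new_trajectory <- function(times, states, theta_trace, terminal_flag) {
  structure(list(times = times, states = states,
                 theta_trace = theta_trace, terminal_flag = terminal_flag),
            class = "fs_trajectory")
}

#' @export
print.fs_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d samples, t in [%g, %g], terminal = %s>\n",
              length(x$times), min(x$times), max(x$times), x$terminal_flag))
  invisible(x)
}

#' @export
as.data.frame.fs_trajectory <- function(x, ...) {
  d <- data.frame(t = x$times,
                  x1 = x$states[, 1], x2 = x$states[, 2])
  if (!is.null(x$theta_trace) && ncol(x$theta_trace) > 0) {
    th <- as.data.frame(x$theta_trace)
    names(th) <- paste0("theta", seq_len(ncol(x$theta_trace)))
    d <- cbind(d, th)
  }
  d
}

out_of_box <- function(x, box, factor = 2) {
  centre <- (box$lower + box$upper) / 2
  half <- (box$upper - box$lower) / 2
  any(abs(x - centre) > factor * half)
}

#' Integrate the deterministic flow
#'
#' Adaptive-step integration of \eqn{\dot x = -G(x)^{-1}\nabla F(x,
#' \theta(t))} with `deSolve`. Integration stops early when the speed drops
#' below `conv_tol` (flag `"converged"`) or when the state leaves the
#' family's domain box by a factor of two (flag `"escaped_domain"`);
#' otherwise the flag is `"max_time"`.
#'
#' @param model a `landscape_model`
#' @param x0 initial phase point
#' @param path a `signal_path`, or a fixed parameter vector (frozen
#'   parameters)
#' @param t_end final time (> 0)
#' @param tol integrator relative/absolute tolerance
#' @param conv_tol speed threshold for convergence
#' @param n_out number of output samples
#' @return an `fs_trajectory`
#' @export
integrate_flow <- function(model, x0, path = model$theta, t_end = 100,
                           tol = 1e-10, conv_tol = 1e-8, n_out = 200L) {
  if (t_end <= 0) stop("t_end must be positive", call. = FALSE)
  path <- as_signal_path(path, t_end)
  fam <- model$family
  metric <- model$metric
  box <- fam$domain_box

  rhs <- function(t, y, parms) {
    th <- theta_at(path, t)
    g <- eval_gradient(fam, y, th)
    list(-solve(metric$evaluate(y), g))
  }
  rootfun <- function(t, y, parms) {
    th <- theta_at(path, t)
    v <- solve(metric$evaluate(y), eval_gradient(fam, y, th))
    centre <- (box$lower + box$upper) / 2
    half <- (box$upper - box$lower) / 2
    c(sqrt(sum(v^2)) - conv_tol,
      max(abs(y - centre) / (2 * half)) - 1)
  }

  times <- seq(0, t_end, length.out = max(2L, n_out))
  sol <- deSolve::lsodar(y = as.numeric(x0), times = times, func = rhs,
                         parms = NULL, rtol = tol, atol = tol,
                         rootfunc = rootfun)
  st <- unname(sol[, 2:3, drop = FALSE])
  tt <- sol[, 1]
  final <- st[nrow(st), ]
  th_final <- theta_at(path, tt[length(tt)])
  v_final <- solve(metric$evaluate(final), eval_gradient(fam, final, th_final))
  flag <- if (sqrt(sum(v_final^2)) <= conv_tol * 1.01) {
    "converged"
  } else if (out_of_box(final, box)) {
    "escaped_domain"
  } else {
    "max_time"
  }
  th_trace <- theta_at(path, tt)
  if (!is.matrix(th_trace)) th_trace <- matrix(th_trace, nrow = length(tt))
  new_trajectory(tt, st, th_trace, flag)
}

# Internal RNG scope guard: runs `expr` under a given seed and restores the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Euler--Maruyama simulation of the noisy flow
#'
#' Fixed-step simulation of \eqn{dX = -G(X)^{-1}\nabla F(X, \theta(t))\,dt
#' + \sigma\, dW} with additive isotropic unit-variance white noise scaled
#' by the model's `sigma`. Identical seeds give identical trajectories.
#'
#' @inheritParams integrate_flow
#' @param dt time step (> 0); default 1e-3
#' @param seed integer seed
#' @param record_every store every k-th step (thins the output)
#' @return an `fs_trajectory`
#' @export
simulate_sde <- function(model, x0, path = model$theta, t_end = 10,
                         dt = 1e-3, seed = 1L, record_every = 10L) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  path <- as_signal_path(path, t_end)
  n_steps <- ceiling(t_end / dt)
  keep <- unique(c(seq(0L, n_steps, by = record_every), n_steps))
  states <- matrix(NA_real_, length(keep), 2L)
  times <- keep * dt
  x <- as.numeric(x0)
  box <- model$family$domain_box
  escaped <- FALSE
  TH <- theta_at(path, (seq_len(n_steps) - 1) * dt)
  if (!is.matrix(TH)) TH <- matrix(TH, nrow = n_steps)
  Ginv_const <- if (model$metric$is_constant) model$metric$inv(c(0, 0)) else NULL
  with_seed(seed, {
    sq <- sqrt(dt) * model$sigma
    ki <- 1L
    if (keep[1] == 0L) { states[1L, ] <- x; ki <- 2L }
    for (s in seq_len(n_steps)) {
      g <- eval_gradient(model$family, x, TH[s, ])
      v <- if (is.null(Ginv_const)) -solve(model$metric$evaluate(x), g)
           else -as.numeric(Ginv_const %*% g)
      x <- x + dt * v + sq * stats::rnorm(2L)
      if (ki <= length(keep) && s == keep[ki]) {
        states[ki, ] <- x
        ki <- ki + 1L
      }
      if (out_of_box(x, box)) {
        escaped <- TRUE
        states[min(ki, length(keep)), ] <- x
        break
      }
    }
  })
  ok <- !is.na(states[, 1])
  states <- states[ok, , drop = FALSE]
  times <- times[ok]
  th_trace <- theta_at(path, times)
  if (!is.matrix(th_trace)) th_trace <- matrix(th_trace, nrow = length(times))
  flag <- if (escaped) "escaped_domain" else "max_time"
  new_trajectory(times, states, th_trace, flag)
}

# Internal: vectorised Euler--Maruyama over a population of cells.
# X is n x 2; gradient evaluation is vectorised through the family.
# Returns the state matrix at each requested observation time.
# theta as the compiled core expects it (two columns; frozen families
# carry their fixed unfolding values)
cpp_theta_for <- function(fam, theta) {
  if (fam$name == "box2_example") c(-3, -1) else as.numeric(theta)
}

sde_population <- function(model, X0, path, t_obs, dt) {
  n <- nrow(X0)
  t_max <- max(t_obs)
  n_steps <- ceiling(t_max / dt)
  obs_steps <- round(t_obs / dt)
  fam <- model$family
  if (!is.null(fam$cpp_id) && model$metric$is_constant) {
    TH <- theta_at(path, (seq_len(n_steps) - 1) * dt)
    if (!is.matrix(TH)) TH <- matrix(TH, nrow = n_steps)
    if (ncol(TH) != 2L) {
      TH <- matrix(rep(cpp_theta_for(fam, numeric(0)), each = n_steps),
                   n_steps, 2L)
    }
    box <- fam$domain_box
    out <- cpp_sde_population(fam$cpp_id, TH, X0, dt, model$sigma,
                              as.integer(obs_steps),
                              model$metric$inv(c(0, 0)),
                              (box$lower + box$upper) / 2,
                              (box$upper - box$lower) / 2)
    names(out) <- as.character(t_obs)
    return(out)
  }
  out <- vector("list", length(t_obs))
  names(out) <- as.character(t_obs)
  X <- X0
  Ginv_const <- if (model$metric$is_constant) model$metric$inv(c(0, 0)) else NULL
  sq <- sqrt(dt) * model$sigma
  TH <- theta_at(path, (seq_len(n_steps) - 1) * dt)
  if (!is.matrix(TH)) TH <- matrix(TH, nrow = n_steps)
  if (any(obs_steps == 0L)) {
    for (k in which(obs_steps == 0L)) out[[k]] <- X
  }
  for (s in seq_len(n_steps)) {
    th <- TH[s, ]
    Gm <- eval_gradient(model$family, X, th)
    if (!is.matrix(Gm)) Gm <- matrix(Gm, nrow = 1L)
    V <- if (!is.null(Ginv_const)) {
      -Gm %*% t(Ginv_const)
    } else {
      t(vapply(seq_len(n), function(i) {
        -solve(model$metric$evaluate(X[i, ]), Gm[i, ])
      }, numeric(2)))
    }
    X <- X + dt * V
    if (sq > 0) X <- X + matrix(stats::rnorm(2L * n, sd = sq), n, 2L)
    hit <- which(obs_steps == s)
    for (k in hit) out[[k]] <- X
  }
  out
}

# Internal: deterministic relaxation of a population under frozen theta,
# used for basin calling. Fixed-step descent with two early exits: all
# speeds below conv_tol, or (when rest points are supplied) every cell
# within attr_tol of an attractor.
relax_population <- function(model, X, theta, dt = 0.01, max_steps = 8000L,
                             conv_tol = 1e-6, rest_points = NULL,
                             attr_tol = 0.02) {
  fam <- model$family
  if (!is.null(fam$cpp_id) && model$metric$is_constant && nrow(X)) {
    A <- if (!is.null(rest_points)) {
      as.matrix(rest_points[rest_points$kind == "attractor", c("x", "y"),
                            drop = FALSE])
    } else matrix(numeric(0), 0L, 2L)
    return(cpp_relax(fam$cpp_id, X, cpp_theta_for(fam, theta), dt,
                     as.integer(max_steps), conv_tol, A, attr_tol,
                     model$metric$inv(c(0, 0))))
  }
  Ginv_const <- if (model$metric$is_constant) model$metric$inv(c(0, 0)) else NULL
  A <- if (!is.null(rest_points)) {
    as.matrix(rest_points[rest_points$kind == "attractor", c("x", "y"),
                          drop = FALSE])
  } else NULL
  Xout <- X
  active <- seq_len(nrow(X))
  for (s in seq_len(max_steps)) {
    if (!length(active)) break
    Gm <- eval_gradient(model$family, X, theta)
    if (!is.matrix(Gm)) Gm <- matrix(Gm, nrow = 1L)
    V <- if (!is.null(Ginv_const)) {
      -Gm %*% t(Ginv_const)
    } else {
      t(vapply(seq_len(nrow(X)), function(i) {
        -solve(model$metric$evaluate(X[i, ]), Gm[i, ])
      }, numeric(2)))
    }
    sp <- sqrt(rowSums(V^2))
    if (max(sp) < conv_tol) break
    # limit the per-step displacement for stability in stiff regions
    fac <- pmin(1, 0.2 / pmax(sp * dt, 1e-12))
    X <- X + (dt * fac) * V
    # retire cells that have reached an attractor's neighbourhood
    if (!is.null(A) && nrow(A) && s %% 25L == 0L) {
      dmin2 <- rep(Inf, nrow(X))
      for (k in seq_len(nrow(A))) {
        dmin2 <- pmin(dmin2, (X[, 1] - A[k, 1])^2 + (X[, 2] - A[k, 2])^2)
      }
      done <- dmin2 < attr_tol^2
      if (any(done)) {
        Xout[active[done], ] <- X[done, , drop = FALSE]
        active <- active[!done]
        X <- X[!done, , drop = FALSE]
      }
    }
  }
  if (length(active)) Xout[active, ] <- X
  Xout
}

#' Export a trajectory to CSV
#'
#' Columns `t`, `x1`, `x2`, `theta1..thetak`.
#' @param traj an `fs_trajectory`
#' @param path output file
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
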