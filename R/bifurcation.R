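# Fold-curve continuation, cusp detection, flip bifurcations, and the
# two-parameter bifurcation atlas.

#' Fold residual at a candidate degenerate point
#'
#' A fold (saddle-node) point satisfies \eqn{\nabla F = 0} together with a
#' rank-deficient Hessian. Both components of the returned pair vanish
#' exactly on fold points.
#'
#' @param family a `potential_family`
#' @param x phase point
#' @param theta parameters
#' @return named numeric vector `c(grad_norm, det_hess)`
#' @export
fold_residual <- function(family, x, theta) {
  g <- eval_gradient(family, x, theta)
  H <- eval_hessian(family, x, theta)
  c(grad_norm = sqrt(sum(g^2)), det_hess = det(H))
}

# Extended defining system for fold continuation in u = (x, y, a, b).
fold_system <- function(family, u) {
  x <- u[1:2]; th <- u[3:4]
  g <- eval_gradient(family, x, th)
  H <- eval_hessian(family, x, th)
  c(g, det(H))
}

num_jacobian <- function(fun, u, h = 1e-6) {
  f0 <- fun(u)
  J <- matrix(0, length(f0), length(u))
  for (i in seq_along(u)) {
    e <- numeric(length(u)); e[i] <- h
    J[, i] <- (fun(u + e) - fun(u - e)) / (2 * h)
  }
  J
}

# Newton correction of u onto {fold_system = 0} along the hyperplane
# orthogonal to `tang` (pseudo-arclength corrector). With tang = NULL the
# minimum-norm (Gauss-Newton) correction is used.
fold_correct <- function(family, u, tang = NULL, tol = 1e-11, maxit = 25L) {
  fun <- function(v) fold_system(family, v)
  for (i in seq_len(maxit)) {
    Fv <- fun(u)
    if (sqrt(sum(Fv^2)) < tol) return(u)
    J <- num_jacobian(fun, u)
    step <- if (is.null(tang)) {
      tryCatch(qr.solve(J, Fv), error = function(e) NULL)
    } else {
      A <- rbind(J, tang)
      tryCatch(solve(A, c(Fv, 0)), error = function(e) NULL)
    }
    if (is.null(step) || !all(is.finite(step))) return(NULL)
    if (sqrt(sum(step^2)) > 1) step <- step / sqrt(sum(step^2))
    u <- u - step
  }
  if (sqrt(sum(fun(u)^2)) < 1e-8) u else NULL
}

fold_tangent <- function(family, u) {
  J <- num_jacobian(function(v) fold_system(family, v), u)
  v <- svd(J, nu = 0, nv = 4)$v[, 4]
  v / sqrt(sum(v^2))
}

theta_in_box <- function(th, box, slack = 0) {
  all(th >= box$lower - slack) && all(th <= box$upper + slack)
}

#' Trace a fold curve by pseudo-arclength continuation
#'
#' Continues the augmented system \eqn{\{\nabla F = 0, \det H = 0\}} in
#' \eqn{(x, y, a, b)} with a tangent predictor and Newton corrector,
#' starting from a point satisfying `fold_residual` below 1e-6. Tracing
#' stops at the parameter-box boundary, when the curve closes into a loop,
#' or after `max_steps` samples per direction.
#'
#' @param family a two-parameter `potential_family`
#' @param seed list with elements `x` (phase point) and `theta`
#' @param box parameter box (list `lower`, `upper`); defaults to the
#'   family's `param_box`
#' @param step arclength step in the extended space
#' @param max_steps cap on samples per direction
#' @return an object of class `fold_curve`: list with `points` (m x 2
#'   matrix of (a,b)), `states` (m x 2 degenerate phase points), `closed`
#' @export
trace_fold_curve <- function(family, seed, box = family$param_box,
                             step = 0.02, max_steps = 2000L) {
  u0 <- fold_correct(family, c(seed$x, seed$theta))
  if (is.null(u0)) stop("seed did not converge onto the fold set",
                        call. = FALSE)
  t0 <- fold_tangent(family, u0)

  run_dir <- function(u, tang, h) {
    pts <- list()
    closed <- FALSE
    for (k in seq_len(max_steps)) {
      hh <- h
      repeat {
        u_try <- fold_correct(family, u + hh * tang, tang)
        if (!is.null(u_try)) break
        hh <- hh / 2
        if (hh < h / 64) return(list(pts = pts, closed = closed,
                                     truncated = TRUE))
      }
      t_new <- fold_tangent(family, u_try)
      if (sum(t_new * tang) < 0) t_new <- -t_new
      u <- u_try; tang <- t_new
      pts[[k]] <- u
      if (!theta_in_box(u[3:4], box)) break
      if (k > 10 && sqrt(sum((u - u0)^2)) < h / 2) { closed <- TRUE; break }
    }
    list(pts = pts, closed = closed, truncated = FALSE)
  }

  fwd <- run_dir(u0, t0, step)
  bwd <- if (fwd$closed) list(pts = list(), closed = TRUE, truncated = FALSE)
         else run_dir(u0, -t0, step)
  us <- c(rev(bwd$pts), list(u0), fwd$pts)
  U <- do.call(rbind, us)
  structure(list(points = U[, 3:4, drop = FALSE],
                 states = U[, 1:2, drop = FALSE],
                 closed = fwd$closed || bwd$closed,
                 truncated = isTRUE(fwd$truncated) || isTRUE(bwd$truncated)),
            class = "fold_curve")
}

#' @export
print.fold_curve <- function(x, ...) {
  cat(sprintf("<fold_curve: %d samples%s>\n", nrow(x$points),
              if (x$closed) ", closed loop" else ""))
  invisible(x)
}

# Third directional derivative of F along the Hessian kernel direction,
# by central differences of the directional first derivative.
kernel_third_derivative <- function(family, x, theta, h = 1e-4) {
  H <- eval_hessian(family, x, theta)
  e <- eigen((H + t(H)) / 2, symmetric = TRUE)
  k <- e$vectors[, which.min(abs(e$values))]
  phi <- function(s) sum(k * eval_gradient(family, x + s * k, theta))
  (phi(h) - 2 * phi(0) + phi(-h)) / h^2
}

cusp_refine <- function(family, u) {
  fun <- function(v) c(fold_system(family, v),
                       kernel_third_derivative(family, v[1:2], v[3:4]))
  for (i in 1:30) {
    Fv <- fun(u)
    if (sqrt(sum(Fv^2)) < 1e-9) return(u)
    J <- num_jacobian(fun, u, h = 1e-5)
    step <- tryCatch(solve(J, Fv), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) return(NULL)
    if (sqrt(sum(step^2)) > 0.5) step <- step * 0.5 / sqrt(sum(step^2))
    u <- u - step
  }
  if (sqrt(sum(fun(u)^2)) < 1e-6) u else NULL
}

match_points <- function(A, B, tol) {
  # rows of A matched to nearest rows of B
  used <- rep(FALSE, nrow(B))
  match_idx <- rep(NA_integer_, nrow(A))
  for (i in seq_len(nrow(A))) {
    d <- sqrt((B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] < tol) {
      match_idx[i] <- j; used[j] <- TRUE
    }
  }
  match_idx
}

#' Detect and classify cusp points on a fold curve
#'
#' Locates parameter-plane turning points of the traced fold curve (where
#' the (a,b)-tangent reverses), refines each by Newton iteration on the
#' augmented system that appends the vanishing third directional
#' derivative along the Hessian kernel, and classifies each cusp by
#' probing rest-point censuses just inside and outside the cusp region:
#' the member of the persisting landscape nearest the newly created pair
#' is an attractor for a standard cusp and a saddle for a dual cusp.
#'
#' @param curve a `fold_curve` with at least 10 samples
#' @param family the family it was traced in
#' @param model optional `landscape_model` (for a non-identity metric)
#' @param probe_delta parameter-space offset of the classification probes
#' @return data frame with columns `a`, `b`, `x`, `y`, `kind`
#'   (`"standard"` or `"dual"`), `n_attr_inside`, `n_attr_outside`
#' @export
detect_cusps <- function(curve, family, model = NULL, probe_delta = NULL) {
  P <- curve$points
  if (nrow(P) < 10L) stop("curve must have at least 10 samples", call. = FALSE)
  if (is.null(model)) model <- landscape_model(family,
                                               rep(0, family$n_params))
  seg <- diff(P)
  len <- sqrt(rowSums(seg^2))
  keep <- len > 1e-12
  seg_u <- seg[keep, , drop = FALSE] / len[keep]
  idx_map <- which(keep)
  cusps <- list()
  if (nrow(seg_u) >= 2L) {
    dots <- rowSums(seg_u[-nrow(seg_u), , drop = FALSE] *
                      seg_u[-1L, , drop = FALSE])
    cand <- which(dots < 0.2)
    # collapse runs of consecutive candidates
    if (length(cand)) {
      grp <- cumsum(c(1, diff(cand) > 3))
      for (g in unique(grp)) {
        i <- cand[grp == g][which.min(dots[cand[grp == g]])]
        row <- idx_map[i] + 1L
        u <- cusp_refine(family, c(curve$states[row, ], P[row, ]))
        if (!is.null(u)) cusps[[length(cusps) + 1L]] <- u
      }
    }
  }
  if (!length(cusps)) {
    return(data.frame(a = numeric(0), b = numeric(0), x = numeric(0),
                      y = numeric(0), kind = character(0),
                      n_attr_inside = integer(0),
                      n_attr_outside = integer(0)))
  }
  # deduplicate refined cusps
  U <- do.call(rbind, cusps)
  keep <- !duplicated(round(U[, 3:4, drop = FALSE], 5))
  U <- U[keep, , drop = FALSE]

  curve_scale <- stats::median(len[len > 1e-12])
  if (is.null(probe_delta)) probe_delta <- max(4 * curve_scale, 1e-3)

  rows <- lapply(seq_len(nrow(U)), function(i) {
    th_c <- U[i, 3:4]
    # classify by crossing a single fold branch a short arclength away
    # from the cusp, perpendicular to the curve (probing through the cusp
    # point itself crosses both folds at once and is degenerate)
    d <- sqrt(rowSums((P - matrix(th_c, nrow(P), 2, byrow = TRUE))^2))
    probe <- function(th) {
      tryCatch(find_rest_points(model, th, grid_n = 16L),
               error = function(e) NULL)
    }
    ref_geom <- function(s_ref) {
      cand <- which(d >= s_ref)
      i_ref <- if (length(cand)) cand[which.min(d[cand])] else which.max(d)
      i2 <- if (i_ref < nrow(P)) i_ref + 1L else i_ref - 1L
      tg <- P[i2, ] - P[i_ref, ]
      nv <- if (sqrt(sum(tg^2)) > 1e-12) perp2(tg / sqrt(sum(tg^2)))
            else c(0, 1)
      list(p = P[i_ref, ], nv = nv)
    }
    classify_side <- function(geom, delta) {
      rp_in <- probe(geom$p + delta * geom$nv)
      rp_out <- probe(geom$p - delta * geom$nv)
      if (is.null(rp_in) || is.null(rp_out)) return(NULL)
      if (abs(nrow(rp_in) - nrow(rp_out)) != 2L) return(NULL)
      if (nrow(rp_in) < nrow(rp_out)) {
        tmp <- rp_in; rp_in <- rp_out; rp_out <- tmp
      }
      # the newly created pair: rest points with no match outside
      # persisting rest points move O(delta) across the probe pair; the
      # colliding pair simply vanishes, so a tight tolerance separates them
      mi <- match_points(as.matrix(rp_in[, c("x", "y")]),
                         as.matrix(rp_out[, c("x", "y")]),
                         tol = 0.15 + 2 * delta)
      new_rows <- which(is.na(mi))
      if (length(new_rows) != 2L) return(NULL)
      persist <- rp_in[setdiff(seq_len(nrow(rp_in)), new_rows), ,
                       drop = FALSE]
      if (!nrow(persist)) return(NULL)
      # the persisting rest point the new pair is attached to: closest
      # approach between any new point and any persisting point
      best <- c(Inf, NA)
      for (nr in new_rows) {
        dd <- sqrt((persist$x - rp_in$x[nr])^2 +
                     (persist$y - rp_in$y[nr])^2)
        if (min(dd) < best[1]) best <- c(min(dd), which.min(dd))
      }
      anchor <- persist[best[2], ]
      list(kind = if (anchor$kind == "attractor") "standard" else "dual",
           n_in = sum(rp_in$kind == "attractor"),
           n_out = sum(rp_out$kind == "attractor"))
    }
    res <- NULL
    # the wedge between the two fold branches has transverse width of
    # order s^(3/2) at arclength s from the cusp: ladder of reference
    # arclengths and probe offsets, accepting the first probe pair whose
    # rest-point counts differ by exactly one created pair
    for (s_fac in c(2.5, 5, 1.2, 10)) {
      s_ref <- min(s_fac * probe_delta, 0.45 * max(d))
      geom <- ref_geom(s_ref)
      for (delta in s_ref^1.5 * c(0.3, 0.15, 0.6, 0.05, 1.2)) {
        res <- classify_side(geom, delta)
        if (!is.null(res)) break
      }
      if (!is.null(res)) break
    }
    if (is.null(res)) res <- list(kind = NA_character_, n_in = NA_integer_,
                                  n_out = NA_integer_)
    data.frame(a = th_c[1], b = th_c[2], x = U[i, 1], y = U[i, 2],
               kind = res$kind, n_attr_inside = res$n_in,
               n_attr_outside = res$n_out)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- flip (heteroclinic) bifurcations -------------------------------------

perp2 <- function(v) c(-v[2], v[1])

# Track the saddle continuing `guess` at parameters `theta`; NULL when it
# has disappeared (fold interference).
track_saddle <- function(model, theta, guess, rest_points = NULL,
                         max_jump = 0.5) {
  rp <- if (is.null(rest_points)) find_rest_points(model, theta) else rest_points
  ns <- nearest_rest_point(rp, guess, kind = "saddle1")
  if (is.null(ns) || ns$dist > max_jump) return(NULL)
  list(rp = rp, id = ns$id, pos = rp_position(rp, ns$id))
}

# Destination of one unstable branch, reported as an index into a fixed
# reference attractor set (matched by position), or NA.
branch_dest_ref <- function(model, theta, saddle_pos, sgn, ref_dir,
                            rest_points, ref_atts, eps = 1e-4,
                            t_max = 400, attr_radius = 1e-3) {
  u <- unstable_direction(model, saddle_pos, theta)
  if (sum(u * ref_dir) < 0) u <- -u
  tr <- integrate_flow(model, saddle_pos + sgn * eps * u, theta,
                       t_end = t_max, n_out = 250L)
  final <- tr$states[nrow(tr$states), ]
  na <- nearest_rest_point(rest_points, final, kind = "attractor")
  if (is.null(na) || na$dist > attr_radius) return(list(idx = NA, traj = tr))
  pos <- rp_position(rest_points, na$id)
  d <- sqrt(rowSums((ref_atts - matrix(pos, nrow(ref_atts), 2,
                                       byrow = TRUE))^2))
  list(idx = if (min(d) < 1.0) which.min(d) else NA, traj = tr)
}

#' Locate a flip bifurcation on a parameter segment
#'
#' A flip is the global bifurcation at which the unstable manifold of a
#' source saddle forms a heteroclinic connection to a sink saddle and
#' switches its destination attractor. Given a segment whose endpoints
#' give different destinations for the tracked branch, the critical
#' parameter is found by bisection on the destination identity.
#'
#' @param model a `landscape_model`
#' @param theta0,theta1 segment endpoints in parameter space
#' @param source_guess approximate position of the source saddle
#' @param tol bisection width in parameter space
#' @param branch `NA` to auto-detect which branch flips, else +1 or -1
#' @return list with `theta_star`, `source_pos`, `sink_pos`,
#'   `approach_dist` (closest approach of the critical branch to the sink
#'   saddle), `dest0`, `dest1`, `sweep_dir`
#' @export
locate_flip <- function(model, theta0, theta1, source_guess, tol = 1e-6,
                        branch = NA) {
  th0 <- as.numeric(theta0); th1 <- as.numeric(theta1)
  s0 <- track_saddle(model, th0, source_guess)
  s1 <- track_saddle(model, th1, source_guess)
  if (is.null(s0) || is.null(s1)) {
    stop("fold interference: the tracked saddle disappears on the segment",
         call. = FALSE)
  }
  ref_atts <- as.matrix(s0$rp[s0$rp$kind == "attractor", c("x", "y")])
  ref_dir <- unstable_direction(model, s0$pos, th0)

  dest_at <- function(th, guess, sgn) {
    s <- track_saddle(model, th, guess)
    if (is.null(s)) return(NULL)
    r <- branch_dest_ref(model, th, s$pos, sgn, ref_dir, s$rp, ref_atts)
    list(idx = r$idx, pos = s$pos, rp = s$rp, traj = r$traj)
  }

  signs <- if (is.na(branch)) c(1, -1) else branch
  sel <- NULL
  for (sgn in signs) {
    d0 <- dest_at(th0, source_guess, sgn)
    d1 <- dest_at(th1, source_guess, sgn)
    if (is.null(d0) || is.null(d1)) next
    if (!is.na(d0$idx) && !is.na(d1$idx) && d0$idx != d1$idx) {
      sel <- list(sgn = sgn, d0 = d0, d1 = d1); break
    }
  }
  if (is.null(sel)) {
    stop("no flip on segment: branch destination does not change",
         call. = FALSE)
  }
  sgn <- sel$sgn
  lo <- th0; hi <- th1
  guess <- sel$d0$pos
  idx_lo <- sel$d0$idx
  while (sqrt(sum((hi - lo)^2)) > tol) {
    mid <- (lo + hi) / 2
    dm <- dest_at(mid, guess, sgn)
    if (is.null(dm)) {
      stop("fold interference during bisection", call. = FALSE)
    }
    guess <- dm$pos
    if (!is.na(dm$idx) && dm$idx == idx_lo) lo <- mid else hi <- mid
  }
  th_star <- (lo + hi) / 2
  s_star <- track_saddle(model, th_star, guess)
  rp <- s_star$rp
  r <- branch_dest_ref(model, th_star, s_star$pos, sgn, ref_dir, rp,
                       ref_atts)
  other_saddles <- rp[rp$kind == "saddle1" & rp$id != s_star$id, ,
                      drop = FALSE]
  approach <- Inf; sink_pos <- NULL
  if (nrow(other_saddles)) {
    tr <- r$traj$states
    for (i in seq_len(nrow(other_saddles))) {
      d <- min(sqrt((tr[, 1] - other_saddles$x[i])^2 +
                      (tr[, 2] - other_saddles$y[i])^2))
      if (d < approach) {
        approach <- d
        sink_pos <- c(other_saddles$x[i], other_saddles$y[i])
      }
    }
  }
  sweep <- (th1 - th0); sweep <- sweep / sqrt(sum(sweep^2))
  list(theta_star = th_star, source_pos = s_star$pos, sink_pos = sink_pos,
       approach_dist = approach, dest0 = sel$d0$idx, dest1 = sel$d1$idx,
       branch = sgn, sweep_dir = sweep)
}

#' Trace a flip curve
#'
#' Continues a flip point through parameter space by repeated
#' `locate_flip` calls on short transverse sweeps. Each endpoint is
#' labelled `"source_end"` or `"sink_end"` when the respective saddle
#' approaches a fold (its Hessian determinant tends to zero),
#' `"box_boundary"` when the curve leaves the box, otherwise `"lost"`.
#'
#' @param model a `landscape_model`
#' @param seed a result of [locate_flip()]
#' @param box parameter box
#' @param step continuation step along the curve
#' @param tol per-point bisection tolerance
#' @param max_steps cap on samples per direction
#' @param degen_tol Hessian-determinant threshold for end labelling
#' @return object of class `flip_curve`: `points` (m x 2), `source_pts`,
#'   `sink_pts`, `endpoints` (length-2 character)
#' @export
trace_flip_curve <- function(model, seed, box = model$family$param_box,
                             step = 0.05, tol = 1e-5, max_steps = 400L,
                             degen_tol = 2e-2) {
  nu0 <- seed$sweep_dir
  tau0 <- perp2(nu0)

  end_label <- function(th, src_pos, snk_pos) {
    fam <- model$family
    d_src <- tryCatch({
      s <- track_saddle(model, th, src_pos)
      if (is.null(s)) 0 else abs(det(eval_hessian(fam, s$pos, th)))
    }, error = function(e) 0)
    d_snk <- tryCatch({
      if (is.null(snk_pos)) return(Inf)
      rp <- find_rest_points(model, th)
      ns <- nearest_rest_point(rp, snk_pos, kind = "saddle1")
      if (is.null(ns) || ns$dist > 0.5) 0
      else abs(det(eval_hessian(fam, rp_position(rp, ns$id), th)))
    }, error = function(e) 0)
    if (!theta_in_box(th, box)) "box_boundary"
    else if (d_src < degen_tol && d_src <= d_snk) "source_end"
    else if (d_snk < degen_tol) "sink_end"
    else "lost"
  }

  run_dir <- function(tau) {
    cur <- seed
    pts <- list(); srcs <- list(); snks <- list()
    label <- "lost"
    for (k in seq_len(max_steps)) {
      th <- cur$theta_star
      if (!theta_in_box(th, box)) { label <- "box_boundary"; break }
      tau_k <- tau
      nu <- perp2(tau_k)
      ok <- FALSE
      for (widen in c(0.6, 1.2, 2.4)) {
        p <- th + step * tau_k
        nxt <- tryCatch(
          locate_flip(model, p - widen * step * nu, p + widen * step * nu,
                      cur$source_pos, tol = tol, branch = cur$branch),
          error = function(e) NULL)
        if (!is.null(nxt)) { ok <- TRUE; break }
      }
      if (!ok) {
        label <- end_label(th, cur$source_pos, cur$sink_pos)
        break
      }
      tau <- nxt$theta_star - th
      tau <- tau / sqrt(sum(tau^2))
      cur <- nxt
      pts[[k]] <- cur$theta_star
      srcs[[k]] <- cur$source_pos
      snks[[k]] <- if (is.null(cur$sink_pos)) c(NA, NA) else cur$sink_pos
    }
    list(pts = pts, srcs = srcs, snks = snks, label = label)
  }

  fwd <- run_dir(tau0)
  bwd <- run_dir(-tau0)
  pts <- rbind(do.call(rbind, rev(bwd$pts)), matrix(seed$theta_star, 1),
               do.call(rbind, fwd$pts))
  srcs <- rbind(do.call(rbind, rev(bwd$srcs)), matrix(seed$source_pos, 1),
                do.call(rbind, fwd$srcs))
  snks <- rbind(do.call(rbind, rev(bwd$snks)),
                matrix(if (is.null(seed$sink_pos)) c(NA, NA)
                       else seed$sink_pos, 1),
                do.call(rbind, fwd$snks))
  structure(list(points = pts, source_pts = srcs, sink_pts = snks,
                 endpoints = c(bwd$label, fwd$label)),
            class = "flip_curve")
}

#' @export
print.flip_curve <- function(x, ...) {
  cat(sprintf("<flip_curve: %d samples, ends: %s / %s>\n", nrow(x$points),
              x$endpoints[1], x$endpoints[2]))
  invisible(x)
}

# ---- atlas ----------------------------------------------------------------

# Does segment p1-p2 cross segment q1-q2? Vectorised over rows of Q1/Q2.
segments_cross <- function(p1, p2, Q1, Q2) {
  d <- p2 - p1
  o1 <- d[1] * (Q1[, 2] - p1[2]) - d[2] * (Q1[, 1] - p1[1])
  o2 <- d[1] * (Q2[, 2] - p1[2]) - d[2] * (Q2[, 1] - p1[1])
  e1 <- Q2[, 1] - Q1[, 1]; e2 <- Q2[, 2] - Q1[, 2]
  o3 <- e1 * (p1[2] - Q1[, 2]) - e2 * (p1[1] - Q1[, 1])
  o4 <- e1 * (p2[2] - Q1[, 2]) - e2 * (p2[1] - Q1[, 1])
  (o1 * o2 < 0) & (o3 * o4 < 0)
}

curve_segments <- function(curves) {
  segs <- lapply(curves, function(cv) {
    P <- cv$points
    if (nrow(P) < 2L) return(NULL)
    list(Q1 = P[-nrow(P), , drop = FALSE], Q2 = P[-1L, , drop = FALSE])
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (!length(segs)) return(NULL)
  list(Q1 = do.call(rbind, lapply(segs, `[[`, "Q1")),
       Q2 = do.call(rbind, lapply(segs, `[[`, "Q2")))
}

#' Assemble the two-parameter bifurcation atlas of a family
#'
#' Scans a parameter box on a regular lattice, seeds and traces all fold
#' curves (rest-point collisions), searches for flip curves (connection
#' changes) between lattice neighbours whose attractor count agrees but
#' whose saddle-branch destinations differ, and partitions the box into
#' regions separated by the traced curves. Each region is probed at up to
#' three interior points and labelled with its attractor count and a
#' decision archetype:
#' \itemize{
#'   \item `monostable`, `bistable` by attractor count;
#'   \item `binary_choice`: tristable with a dual cusp on its boundary
#'     (the central attractor is destroyed by one of two folds);
#'   \item `binary_flip`: tristable bordered by a flip curve (a single
#'     escape route that flips between the committed fates);
#'   \item `tristable_other` otherwise; `multistable` beyond three.
#' }
#'
#' @param family a two-parameter `potential_family`
#' @param box parameter box; defaults to the family's `param_box`
#' @param resolution lattice points per axis
#' @param metric metric used for the connection analysis
#' @param fold_step continuation step for fold curves
#' @param flip_scan search for flip curves as well (slower)
#' @param flip_tol bisection tolerance used during flip tracing
#' @return object of class `bifurcation_set` with `fold_curves`,
#'   `flip_curves`, `cusp_points`, `regions`, `grid`
#' @export
build_atlas <- function(family, box = family$param_box, resolution = 22L,
                        metric = identity_metric(2L), fold_step = 0.02,
                        flip_scan = TRUE, flip_tol = 1e-4) {
  model <- landscape_model(family, rep(0, family$n_params), metric = metric)
  as_ <- seq(box$lower[1], box$upper[1], length.out = resolution)
  bs_ <- seq(box$lower[2], box$upper[2], length.out = resolution)
  cell_w <- max(as_[2] - as_[1], bs_[2] - bs_[1])
  grid <- expand.grid(a = as_, b = bs_)
  census <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    census[[i]] <- tryCatch(
      find_rest_points(model, as.numeric(grid[i, ]), grid_n = 12L),
      error = function(e) NULL)
  }
  n_rp <- vapply(census, function(z) if (is.null(z)) NA_integer_
                 else nrow(z), integer(1))
  n_att <- vapply(census, function(z) if (is.null(z)) NA_integer_
                  else sum(z$kind == "attractor"), integer(1))

  idx <- function(i, j) (j - 1L) * resolution + i
  neighbours <- list()
  for (j in seq_len(resolution)) for (i in seq_len(resolution)) {
    if (i < resolution) neighbours[[length(neighbours) + 1L]] <-
        c(idx(i, j), idx(i + 1L, j))
    if (j < resolution) neighbours[[length(neighbours) + 1L]] <-
        c(idx(i, j), idx(i, j + 1L))
  }

  # ---- fold curves: seed where the rest-point count changes
  fold_curves <- list()
  on_existing <- function(th) {
    for (cv in fold_curves) {
      d <- sqrt(rowSums((cv$points - matrix(th, nrow(cv$points), 2,
                                            byrow = TRUE))^2))
      if (min(d) < 3 * fold_step) return(TRUE)
    }
    FALSE
  }
  for (nb in neighbours) {
    i1 <- nb[1]; i2 <- nb[2]
    if (is.na(n_rp[i1]) || is.na(n_rp[i2]) || n_rp[i1] == n_rp[i2]) next
    th_lo <- as.numeric(grid[i1, ]); th_hi <- as.numeric(grid[i2, ])
    c_lo <- census[[i1]]; c_hi <- census[[i2]]
    if (nrow(c_lo) < nrow(c_hi)) {
      tmp <- th_lo; th_lo <- th_hi; th_hi <- tmp
      tmp <- c_lo; c_lo <- c_hi; c_hi <- tmp
    }
    # bisect the segment on the rest-point count
    for (it in 1:25) {
      mid <- (th_lo + th_hi) / 2
      cm <- tryCatch(find_rest_points(model, mid, grid_n = 12L),
                     error = function(e) NULL)
      if (!is.null(cm) && nrow(cm) == nrow(c_lo)) {
        th_lo <- mid; c_lo <- cm
      } else th_hi <- mid
      if (sqrt(sum((th_hi - th_lo)^2)) < 1e-4) break
    }
    # colliding pair on the rich side: two closest rest points
    M <- as.matrix(c_lo[, c("x", "y")])
    if (nrow(M) < 2L) next
    D <- as.matrix(stats::dist(M))
    diag(D) <- Inf
    pair <- which(D == min(D), arr.ind = TRUE)[1, ]
    x_seed <- colMeans(M[pair, , drop = FALSE])
    if (on_existing(th_lo)) next
    cv <- tryCatch(
      trace_fold_curve(family, list(x = x_seed, theta = th_lo), box,
                       step = fold_step),
      error = function(e) NULL)
    if (!is.null(cv) && nrow(cv$points) >= 5L) {
      fold_curves[[length(fold_curves) + 1L]] <- cv
    }
  }

  # ---- cusp points on the fold curves
  cusp_points <- do.call(rbind, c(list(
    data.frame(a = numeric(0), b = numeric(0), x = numeric(0),
               y = numeric(0), kind = character(0),
               n_attr_inside = integer(0), n_attr_outside = integer(0),
               curve = integer(0))),
    lapply(seq_along(fold_curves), function(k) {
      cp <- tryCatch(detect_cusps(fold_curves[[k]], family, model),
                     error = function(e) NULL)
      if (is.null(cp) || !nrow(cp)) return(NULL)
      cp$curve <- k
      cp
    })))

  # ---- flip curves: neighbours with equal counts but different
  # saddle-branch destination patterns
  flip_curves <- list()
  if (flip_scan) {
    conn_sig <- function(i) {
      rp <- census[[i]]
      th <- as.numeric(grid[i, ])
      sads <- rp[rp$kind == "saddle1", , drop = FALSE]
      atts <- as.matrix(rp[rp$kind == "attractor", c("x", "y")])
      sig <- list()
      for (s in seq_len(nrow(sads))) {
        pos <- c(sads$x[s], sads$y[s])
        dests <- tryCatch({
          u <- unstable_direction(model, pos, th)
          vapply(c(1, -1), function(sgn) {
            r <- branch_dest_ref(model, th, pos, sgn, u, rp, atts)
            if (is.na(r$idx)) NA_integer_ else as.integer(r$idx)
          }, integer(1))
        }, error = function(e) c(NA_integer_, NA_integer_))
        sig[[s]] <- list(pos = pos, dests = sort(dests, na.last = TRUE))
      }
      list(saddles = sig, atts = atts)
    }
    sig_cache <- new.env()
    get_sig <- function(i) {
      key <- as.character(i)
      if (!is.null(sig_cache[[key]])) return(sig_cache[[key]])
      s <- tryCatch(conn_sig(i), error = function(e) NULL)
      sig_cache[[key]] <- s
      s
    }
    on_existing_flip <- function(th, tol) {
      for (cv in flip_curves) {
        d <- sqrt(rowSums((cv$points - matrix(th, nrow(cv$points), 2,
                                              byrow = TRUE))^2))
        if (min(d) < tol) return(TRUE)
      }
      FALSE
    }
    for (nb in neighbours) {
      i1 <- nb[1]; i2 <- nb[2]
      if (is.na(n_att[i1]) || is.na(n_att[i2])) next
      if (n_att[i1] != n_att[i2] || n_att[i1] < 2L) next
      if (is.na(n_rp[i1]) || n_rp[i1] != n_rp[i2]) next
      g1 <- get_sig(i1); g2 <- get_sig(i2)
      if (is.null(g1) || is.null(g2)) next
      s1 <- g1$saddles; s2 <- g2$saddles
      if (length(s1) != length(s2)) next
      # express the neighbour's destination indices in terms of the first
      # point's attractor labels (matched by position), so a label swap
      # caused by potential reordering cannot mask a genuine flip
      a_map <- match_points(g2$atts, g1$atts, tol = 1.0)
      if (anyNA(a_map)) next
      moved <- NULL
      for (k in seq_along(s1)) {
        pos1 <- s1[[k]]$pos
        dmin <- Inf; k2 <- NA
        for (l in seq_along(s2)) {
          d <- sqrt(sum((s2[[l]]$pos - pos1)^2))
          if (d < dmin) { dmin <- d; k2 <- l }
        }
        if (is.na(k2) || dmin > 0.5) next
        d2m <- sort(a_map[s2[[k2]]$dests], na.last = TRUE)
        if (!identical(as.integer(s1[[k]]$dests), as.integer(d2m)) &&
            !anyNA(c(s1[[k]]$dests, d2m))) {
          moved <- pos1; break
        }
      }
      if (is.null(moved)) next
      th1 <- as.numeric(grid[i1, ]); th2 <- as.numeric(grid[i2, ])
      if (on_existing_flip((th1 + th2) / 2, 1.2 * cell_w)) next
      fl <- tryCatch(
        locate_flip(model, th1, th2, moved, tol = flip_tol),
        error = function(e) NULL)
      if (is.null(fl)) next
      if (on_existing_flip(fl$theta_star, 3 * fold_step)) next
      cv <- tryCatch(
        trace_flip_curve(model, fl, box, step = 4 * fold_step,
                         tol = flip_tol),
        error = function(e) NULL)
      if (!is.null(cv) && nrow(cv$points) >= 3L) {
        flip_curves[[length(flip_curves) + 1L]] <- cv
      }
    }
  }

  # ---- regions: lattice components not separated by any traced curve
  all_curves <- c(fold_curves, flip_curves)
  segs <- curve_segments(all_curves)
  comp <- rep(NA_integer_, nrow(grid))
  valid <- which(!is.na(n_att))
  nxt <- 1L
  adj <- vector("list", nrow(grid))
  for (nb in neighbours) {
    i1 <- nb[1]; i2 <- nb[2]
    if (is.na(n_att[i1]) || is.na(n_att[i2])) next
    crossed <- if (is.null(segs)) FALSE else {
      any(segments_cross(as.numeric(grid[i1, ]), as.numeric(grid[i2, ]),
                         segs$Q1, segs$Q2))
    }
    if (!crossed && n_rp[i1] == n_rp[i2]) {
      adj[[i1]] <- c(adj[[i1]], i2)
      adj[[i2]] <- c(adj[[i2]], i1)
    }
  }
  for (v in valid) {
    if (!is.na(comp[v])) next
    queue <- v; comp[v] <- nxt
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[cur]]) if (is.na(comp[w])) {
        comp[w] <- nxt; queue <- c(queue, w)
      }
    }
    nxt <- nxt + 1L
  }

  near_curve <- function(cells, curves, tol) {
    if (!length(curves)) return(FALSE)
    G <- as.matrix(grid[cells, , drop = FALSE])
    for (cv in curves) {
      P <- cv$points
      for (r in seq_len(nrow(G))) {
        d <- sqrt((P[, 1] - G[r, 1])^2 + (P[, 2] - G[r, 2])^2)
        if (min(d) < tol) return(TRUE)
      }
    }
    FALSE
  }
  regions <- lapply(seq_len(max(comp, na.rm = TRUE)), function(rid) {
    cells <- which(comp == rid)
    counts <- n_att[cells]
    n <- as.integer(stats::median(counts))
    probes <- cells[round(seq(1, length(cells),
                              length.out = min(3L, length(cells))))]
    ambiguous <- length(unique(n_att[probes])) > 1L
    arch <- if (ambiguous) "ambiguous"
    else if (n <= 1L) "monostable"
    else if (n == 2L) "bistable"
    else if (n == 3L) {
      has_flip <- near_curve(cells, flip_curves, 2.5 * cell_w)
      has_dual <- nrow(cusp_points) > 0 &&
        any(vapply(which(cusp_points$kind %in% "dual"), function(ci) {
          d <- sqrt((grid$a[cells] - cusp_points$a[ci])^2 +
                      (grid$b[cells] - cusp_points$b[ci])^2)
          min(d) < 2.5 * cell_w
        }, logical(1)))
      if (has_flip) "binary_flip"
      else if (has_dual) "binary_choice"
      else "tristable_other"
    } else "multistable"
    list(id = rid, cells = cells, n_attractors = n,
         archetype = arch, probe_cells = probes)
  })

  structure(list(fold_curves = fold_curves, flip_curves = flip_curves,
                 cusp_points = cusp_points, regions = regions,
                 grid = cbind(grid, n_rest = n_rp, n_attr = n_att,
                              region = comp),
                 box = box, resolution = resolution),
            class = "bifurcation_set")
}

#' @export
print.bifurcation_set <- function(x, ...) {
  cat(sprintf(
    "<bifurcation_set: %d fold curve(s), %d flip curve(s), %d cusp(s), %d region(s)>\n",
    length(x$fold_curves), length(x$flip_curves),
    nrow(x$cusp_points), length(x$regions)))
  for (r in x$regions) {
    cat(sprintf("  region %d: %d attractor(s), %s (%d lattice cells)\n",
                r$id, r$n_attractors, r$archetype, length(r$cells)))
  }
  invisible(x)
}

#' Codimension-one mechanism types present in an atlas
#'
#' Generic one-parameter decision events come in exactly two kinds:
#' rest-point collisions (folds) and connection changes (flips). This
#' reports which of the two appear among the traced curves.
#'
#' @param atlas a `bifurcation_set`
#' @return character vector, subset of
#'   `c("connection_change", "rest_point_collision")`
#' @export
mechanism_types <- function(atlas) {
  out <- character(0)
  if (length(atlas$fold_curves)) out <- c(out, "rest_point_collision")
  if (length(atlas$flip_curves)) out <- c(out, "connection_change")
  sort(out)
}

#' Export an atlas to JSON
#' @param atlas a `bifurcation_set`
#' @param path output file
#' @export
write_atlas <- function(atlas, path) {
  obj <- list(
    box = atlas$box,
    fold_curves = lapply(atlas$fold_curves, function(cv) {
      list(points = unname(apply(cv$points, 1, as.list)), closed = cv$closed)
    }),
    flip_curves = lapply(atlas$flip_curves, function(cv) {
      list(points = unname(apply(cv$points, 1, as.list)),
           endpoints = cv$endpoints)
    }),
    cusp_points = atlas$cusp_points,
    regions = lapply(atlas$regions, function(r) {
      list(id = r$id, n_attractors = r$n_attractors,
           archetype = r$archetype, n_cells = length(r$cells))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
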