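# Rest points, unstable manifolds, basins, decision graphs.

newton_root <- function(fam, x0, theta, tol = 1e-12, maxit = 60L) {
  x <- as.numeric(x0)
  box <- fam$domain_box
  for (i in seq_len(maxit)) {
    g <- eval_gradient(fam, x, theta)
    if (!all(is.finite(g))) return(NULL)
    if (sqrt(sum(g^2)) < tol) return(x)
    H <- eval_hessian(fam, x, theta)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) return(NULL)
    # trust-region style cap on the step length
    len <- sqrt(sum(step^2))
    if (len > 0.5) step <- step * (0.5 / len)
    x <- x - step
    if (out_of_box(x, box)) return(NULL)
  }
  g <- eval_gradient(fam, x, theta)
  if (sqrt(sum(g^2)) < 1e-8) x else NULL
}

# Vectorised damped Newton from many starts at once; needs fam$hess_v.
newton_multistart <- function(fam, X, theta, dedup_tol = 1e-5,
                              maxit = 40L, tol = 1e-12) {
  box <- fam$domain_box
  colnames(X) <- NULL
  done <- matrix(numeric(0), 0L, 2L)
  for (it in seq_len(maxit)) {
    if (nrow(X) == 0L) break
    Gm <- fam$grad(X, theta)
    if (!is.matrix(Gm)) Gm <- matrix(Gm, nrow = 1L)
    gn2 <- Gm[, 1]^2 + Gm[, 2]^2
    conv <- gn2 < tol^2
    if (any(conv)) {
      done <- rbind(done, X[conv, , drop = FALSE])
      X <- X[!conv, , drop = FALSE]
      Gm <- Gm[!conv, , drop = FALSE]
      if (nrow(X) == 0L) break
    }
    Hv <- fam$hess_v(X, theta)
    det <- Hv[, 1] * Hv[, 3] - Hv[, 2]^2
    sx <- (Hv[, 3] * Gm[, 1] - Hv[, 2] * Gm[, 2]) / det
    sy <- (Hv[, 1] * Gm[, 2] - Hv[, 2] * Gm[, 1]) / det
    len <- sqrt(sx^2 + sy^2)
    cap <- pmin(1, 0.5 / pmax(len, 1e-300))
    X <- cbind(X[, 1] - cap * sx, X[, 2] - cap * sy)
    keep <- is.finite(X[, 1]) & is.finite(X[, 2]) &
      abs(X[, 1] - (box$lower[1] + box$upper[1]) / 2) <=
        (box$upper[1] - box$lower[1]) &
      abs(X[, 2] - (box$lower[2] + box$upper[2]) / 2) <=
        (box$upper[2] - box$lower[2])
    X <- X[keep, , drop = FALSE]
  }
  if (nrow(X)) {
    Gm <- fam$grad(X, theta)
    if (!is.matrix(Gm)) Gm <- matrix(Gm, nrow = 1L)
    done <- rbind(done, X[Gm[, 1]^2 + Gm[, 2]^2 < 1e-18, , drop = FALSE])
  }
  out <- list()
  for (i in seq_len(nrow(done))) {
    r <- done[i, ]
    dup <- FALSE
    for (q in out) if (sqrt(sum((q - r)^2)) < dedup_tol) { dup <- TRUE; break }
    if (!dup) out[[length(out) + 1L]] <- r
  }
  out
}

classify_rest_point <- function(fam, x, theta, eig_tol = 1e-9) {
  H <- eval_hessian(fam, x, theta)
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
  idx <- sum(ev < -eig_tol)
  kind <- c("attractor", "saddle1", "repellor")[idx + 1L]
  list(morse_index = idx, kind = kind, eigs = sort(ev), degenerate = any(abs(ev) <= eig_tol))
}

#' Locate and classify all rest points of a landscape
#'
#' Multistart Newton iteration on \eqn{\nabla F = 0} from a `grid_n` x
#' `grid_n` lattice over the family's domain box. Converged roots are
#' deduplicated at `dedup_tol` and classified by the inertia of the Hessian
#' of \eqn{F}: Morse index 0 = attractor, 1 = index-1 saddle, 2 = repellor.
#' The Morse index computed from the Hessian alone equals the number of
#' unstable directions of the flow \eqn{-G^{-1}\nabla F} for any SPD metric
#' (Sylvester's law of inertia), so rest-point classification does not
#' depend on the metric.
#'
#' @param model a `landscape_model` (only its family is used)
#' @param theta parameters (defaults to the model's)
#' @param grid_n lattice resolution per axis (>= 8)
#' @param dedup_tol positional deduplication tolerance
#' @param strict retry at doubled lattice resolution when the
#'   Poincare-Hopf index sum shows that a root was missed (default);
#'   `FALSE` accepts the census as found, which is faster and adequate
#'   when only the attractors matter
#' @return a data frame with columns `id`, `x`, `y`, `potential`,
#'   `morse_index`, `kind`, `eig1`, `eig2`, sorted by potential value
#' @export
find_rest_points <- function(model, theta = model$theta, grid_n = 12L,
                             dedup_tol = 1e-5, strict = TRUE) {
  fam <- if (inherits(model, "landscape_model")) model$family else model
  if (grid_n < 8L) stop("grid_n must be at least 8", call. = FALSE)
  theta <- check_theta(fam, theta)
  box <- fam$domain_box
  xs <- seq(box$lower[1], box$upper[1], length.out = grid_n)
  ys <- seq(box$lower[2], box$upper[2], length.out = grid_n)
  roots <- if (is.null(fam$hess_v)) {
    rs <- list()
    for (x0 in xs) for (y0 in ys) {
      r <- newton_root(fam, c(x0, y0), theta)
      if (is.null(r)) next
      dup <- FALSE
      for (q in rs) if (sqrt(sum((q - r)^2)) < dedup_tol) { dup <- TRUE; break }
      if (!dup) rs[[length(rs) + 1L]] <- r
    }
    rs
  } else {
    newton_multistart(fam, as.matrix(expand.grid(xs, ys)), theta, dedup_tol)
  }
  if (length(roots) == 0L) {
    stop("no rest points found; a confined potential must have a minimum",
         call. = FALSE)
  }
  M <- do.call(rbind, roots)
  cls <- lapply(roots, function(r) classify_rest_point(fam, r, theta))
  out <- data.frame(
    x = M[, 1], y = M[, 2],
    potential = as.numeric(eval_potential(fam, M, theta)),
    morse_index = vapply(cls, `[[`, 0L, "morse_index"),
    kind = vapply(cls, `[[`, "", "kind"),
    eig1 = vapply(cls, function(c) c$eigs[1], numeric(1)),
    eig2 = vapply(cls, function(c) c$eigs[2], numeric(1)),
    stringsAsFactors = FALSE)
  # Poincare-Hopf check for a confining planar potential: the rest-point
  # indices (+1 extrema, -1 saddles) must sum to 1. If not, some root with
  # a small Newton basin was missed: refine the start lattice and retry.
  index_sum <- sum(ifelse(out$morse_index == 1L, -1L, 1L))
  if (strict && index_sum != 1L && grid_n < 96L) {
    return(find_rest_points(model, theta, grid_n = grid_n * 2L, dedup_tol))
  }
  out <- out[order(out$potential, out$x, out$y), , drop = FALSE]
  out$id <- paste0("r", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("id", "x", "y", "potential", "morse_index", "kind", "eig1", "eig2")]
}

rp_position <- function(rest_points, id) {
  i <- match(id, rest_points$id)
  c(rest_points$x[i], rest_points$y[i])
}

nearest_rest_point <- function(rest_points, x, kind = NULL) {
  rp <- rest_points
  if (!is.null(kind)) rp <- rp[rp$kind %in% kind, , drop = FALSE]
  if (nrow(rp) == 0L) return(NULL)
  d <- sqrt((rp$x - x[1])^2 + (rp$y - x[2])^2)
  i <- which.min(d)
  list(id = rp$id[i], dist = d[i])
}

# Unstable eigendirection of the linearised flow -G^{-1} H at a saddle.
unstable_direction <- function(model, x, theta = model$theta) {
  H <- eval_hessian(model$family, x, theta)
  G <- eval_metric(model$metric, x)
  A <- -solve(G, H)
  e <- eigen(A)
  vals <- Re(e$values)
  i <- which.max(vals)
  if (vals[i] <= 0) stop("rest point has no unstable direction", call. = FALSE)
  u <- Re(e$vectors[, i])
  u / sqrt(sum(u^2))
}

#' Trace the unstable manifold of an index-1 saddle
#'
#' The two branches of the 1D unstable manifold are the escape routes of
#' the saddle: they are obtained by integrating the flow from the saddle
#' position offset by \eqn{\pm\epsilon u}, where \eqn{u} is the unit
#' eigenvector of the linearised field \eqn{-G^{-1}H} with positive
#' eigenvalue. Each branch reports its destination: an attractor id, the
#' label `"near_saddle"` if it stalls within `attr_radius` of a saddle
#' (the hallmark of a heteroclinic flip connection), or `"escaped"`.
#'
#' @param model a `landscape_model`
#' @param saddle saddle id (row of `rest_points`) or a phase point
#' @param theta parameters
#' @param rest_points optional precomputed rest points
#' @param eps initial offset along the unstable eigenvector
#' @param t_max maximum integration time per branch
#' @param attr_radius attractor-proximity radius for destination calling
#' @return list of two branches; each branch is a list with
#'   `direction_sign`, `polyline`, `destination`, `terminal_flag`
#' @export
unstable_manifold <- function(model, saddle, theta = model$theta,
                              rest_points = NULL, eps = 1e-4, t_max = 400,
                              attr_radius = 1e-3) {
  if (is.null(rest_points)) rest_points <- find_rest_points(model, theta)
  if (is.character(saddle)) {
    pos <- rp_position(rest_points, saddle)
    kind <- rest_points$kind[match(saddle, rest_points$id)]
    if (!identical(kind, "saddle1")) {
      stop("unstable_manifold requires an index-1 saddle", call. = FALSE)
    }
  } else {
    pos <- as.numeric(saddle)
  }
  u <- unstable_direction(model, pos, theta)
  lapply(c(1, -1), function(sgn) {
    tr <- integrate_flow(model, pos + sgn * eps * u, theta, t_end = t_max,
                         n_out = 400L)
    final <- tr$states[nrow(tr$states), ]
    na <- nearest_rest_point(rest_points, final, kind = "attractor")
    ns <- nearest_rest_point(rest_points, final, kind = "saddle1")
    dest <- if (!is.null(na) && na$dist < attr_radius) {
      na$id
    } else if (!is.null(ns) && ns$dist < attr_radius) {
      "near_saddle"
    } else {
      "escaped"
    }
    list(direction_sign = sgn, polyline = tr$states, destination = dest,
         terminal_flag = tr$terminal_flag)
  })
}

#' Basin membership of a phase point
#'
#' Integrates the frozen-parameter flow from `x` to convergence and
#' returns the id of the attractor reached. Points converging within
#' `saddle_band` of a saddle are reported as `"undecidable"` (they lie on
#' a stable manifold, the measure-zero ridge between basins).
#'
#' @inheritParams unstable_manifold
#' @param x phase point inside the domain box
#' @param saddle_band half-width of the undecidable band around saddles
#' @return attractor id, `"undecidable"`, or an error if the trajectory
#'   escapes
#' @export
basin_of <- function(model, x, theta = model$theta, rest_points = NULL,
                     attr_radius = 1e-3, saddle_band = 1e-6) {
  if (is.null(rest_points)) rest_points <- find_rest_points(model, theta)
  na0 <- nearest_rest_point(rest_points, x, kind = "attractor")
  if (!is.null(na0) && na0$dist < attr_radius) return(na0$id)
  ns0 <- nearest_rest_point(rest_points, x, kind = "saddle1")
  if (!is.null(ns0) && ns0$dist < saddle_band) return("undecidable")
  tr <- integrate_flow(model, x, theta, t_end = 500)
  final <- tr$states[nrow(tr$states), ]
  na <- nearest_rest_point(rest_points, final, kind = "attractor")
  if (!is.null(na) && na$dist < attr_radius) return(na$id)
  ns <- nearest_rest_point(rest_points, final, kind = "saddle1")
  if (!is.null(ns) && ns$dist < attr_radius) return("undecidable")
  stop("basin_of: trajectory did not converge to an attractor (flag ",
       tr$terminal_flag, ")", call. = FALSE)
}

#' Build the decision graph of a landscape
#'
#' Nodes are the attractors; an edge joins two attractors if some index-1
#' saddle's unstable-manifold branches end at the two of them. Multiple
#' saddles connecting the same pair are collapsed to a single edge, and
#' saddles whose two branches reach the same attractor produce no edge
#' (self-loops are deleted). The result lists every possible transition in
#' the landscape.
#'
#' @inheritParams unstable_manifold
#' @return an object of class `decision_graph`: list with `nodes`, `edges`
#'   (data frame `from`, `to`), `saddle_map`, `rest_points`, `complete`
#' @export
decision_graph <- function(model, theta = model$theta, rest_points = NULL,
                           eps = 1e-4, t_max = 400) {
  if (is.null(rest_points)) rest_points <- find_rest_points(model, theta)
  atts <- rest_points$id[rest_points$kind == "attractor"]
  sads <- rest_points$id[rest_points$kind == "saddle1"]
  edges <- list()
  saddle_map <- list()
  complete <- TRUE
  for (s in sads) {
    br <- unstable_manifold(model, s, theta, rest_points, eps = eps,
                            t_max = t_max)
    d1 <- br[[1]]$destination; d2 <- br[[2]]$destination
    if (identical(d1, "escaped") || identical(d2, "escaped")) {
      complete <- FALSE
      next
    }
    if (d1 %in% atts && d2 %in% atts && d1 != d2) {
      key <- paste(sort(c(d1, d2)), collapse = "|")
      edges[[key]] <- sort(c(d1, d2))
      saddle_map[[key]] <- c(saddle_map[[key]], s)
    } else {
      # both branches at one attractor (or a flip point): retained in the
      # saddle map under a loop key but contributes no edge
      key <- paste0("loop:", s)
      saddle_map[[key]] <- s
    }
  }
  ed <- if (length(edges)) {
    do.call(rbind, lapply(unname(edges), function(e) {
      data.frame(from = e[1], to = e[2])
    }))
  } else {
    data.frame(from = character(0), to = character(0))
  }
  structure(list(nodes = atts, edges = ed, saddle_map = saddle_map,
                 rest_points = rest_points, complete = complete),
            class = "decision_graph")
}

#' @export
print.decision_graph <- function(x, ...) {
  cat(sprintf("<decision_graph: %d attractor(s), %d edge(s)%s>\n",
              length(x$nodes), nrow(x$edges),
              if (x$complete) "" else ", incomplete"))
  if (nrow(x$edges)) {
    for (i in seq_len(nrow(x$edges))) {
      cat(" ", x$edges$from[i], "--", x$edges$to[i], "\n")
    }
  }
  invisible(x)
}

# igraph view of a decision graph (unlabelled topology).
dg_as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = length(g$nodes), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = g$nodes)
  if (nrow(g$edges)) {
    ig <- igraph::add_edges(ig, rbind(match(g$edges$from, g$nodes),
                                      match(g$edges$to, g$nodes)))
  }
  ig
}

#' Export a decision graph
#'
#' @param g a `decision_graph`
#' @param path output file
#' @param format `"json"` (adjacency + saddle annotations) or `"dot"`
#' @export
write_decision_graph <- function(g, path, format = c("json", "dot")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(nodes = g$nodes,
                edges = if (nrow(g$edges)) {
                  lapply(seq_len(nrow(g$edges)), function(i) {
                    key <- paste(c(g$edges$from[i], g$edges$to[i]),
                                 collapse = "|")
                    list(from = g$edges$from[i], to = g$edges$to[i],
                         saddles = as.list(g$saddle_map[[key]]))
                  })
                } else list(),
                complete = g$complete)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    lines <- c("graph decision {",
               paste0("  \"", g$nodes, "\";"),
               if (nrow(g$edges)) {
                 paste0("  \"", g$edges$from, "\" -- \"", g$edges$to, "\";")
               },
               "}")
    writeLines(lines, path)
  }
  invisible(path)
}
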