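# Shared fixtures and independent oracles used across the suite.

catalogue_families <- c("elliptic_umbilic", "box2_example", "cusp1d",
                        "dual_cusp1d", "flip_with_cusp")

box2_metric_minus <- function() {
  riemannian_metric(matrix(c(1, -0.6, -0.6, 1), 2, 2))
}
box2_metric_plus <- function() {
  riemannian_metric(matrix(c(1, 0.6, 0.6, 1), 2, 2))
}

random_theta <- function(fam, lo = -3, hi = 3) {
  stats::runif(fam$n_params, lo, hi)
}

random_spd <- function() {
  A <- matrix(stats::rnorm(4), 2, 2)
  S <- crossprod(A) + diag(2) * 0.3
  (S + t(S)) / 2
}

# Elliptic-umbilic binary-flip study: a ramp destroys the progenitor
# attractor on the symmetry axis; cells split between the two committed
# fates. Used by the population and fitting suites.
eu_flip_refs <- function() {
  list(A = c(2.2, 2.96), B = c(2.2, -2.96), P = c(-3.25, 0))
}

# observation grid for fitting studies: crossing times 45.2/|a_end| of the
# progenitor fold spaced ~0.2 apart in a_end across the prior range
eu_fit_t_obs <- function() c(6.1, 6.3, 6.5, 6.65, 6.85, 7.05, 7.3,
                             7.55, 7.8, 9)

eu_flip_schedule <- function(n_cells, b_off = 0, a_end = -6,
                             t_obs = 9, dt = 0.02) {
  t_last <- max(9, max(t_obs))
  path <- signal_path(c(0, 8, t_last),
                      cbind(c(0, a_end, a_end), c(b_off, b_off, b_off)))
  signal_schedule(list(ramp = path), t_obs = t_obs, n_cells = n_cells,
                  x0 = list(point = c(-3.2466, 0), sd = 0.05),
                  fate_refs = eu_flip_refs(), dt = dt)
}

# free signal-path knots for the flip-ramp fit: parameter 1 is the ramp
# target a_end, parameter 2 the constant offset b_off
eu_flip_free_knots <- function() {
  list(list(condition = "ramp", knot = 2, column = 1, param = 1),
       list(condition = "ramp", knot = 3, column = 1, param = 1),
       list(condition = "ramp", knot = 1, column = 2, param = 2),
       list(condition = "ramp", knot = 2, column = 2, param = 2),
       list(condition = "ramp", knot = 3, column = 2, param = 2))
}

eu_flip_model <- function(sigma = 0.2) {
  landscape_model(make_family("elliptic_umbilic"), c(0, 0), sigma = sigma)
}

# ---- independent graph-census oracle --------------------------------------
# Second canonicalization: minimum edge-set bitmask over all vertex
# permutations, with direct edge-subset enumeration. Kept free of the
# package's own canonical form (which uses BLISS via igraph).

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

oracle_connected <- function(n, edges_sel, EP) {
  if (n == 1L) return(TRUE)
  E <- EP[edges_sel, , drop = FALSE]
  if (!nrow(E)) return(FALSE)
  reach <- rep(FALSE, n); reach[1L] <- TRUE
  repeat {
    grew <- FALSE
    for (r in seq_len(nrow(E))) {
      if (xor(reach[E[r, 1]], reach[E[r, 2]])) {
        reach[E[r, 1]] <- reach[E[r, 2]] <- TRUE
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  all(reach)
}

oracle_census_count <- function(n) {
  if (n == 1L) return(1L)
  EP <- t(utils::combn(n, 2L))
  ne <- nrow(EP)
  perms <- all_permutations(n)
  # edge index permutation for each vertex permutation
  edge_id <- function(i, j) {
    a <- pmin(i, j); b <- pmax(i, j)
    match(paste(a, b), paste(EP[, 1], EP[, 2]))
  }
  maps <- matrix(vapply(perms, function(p) edge_id(p[EP[, 1]], p[EP[, 2]]),
                        integer(ne)), nrow = ne)
  # all edge subsets as a 2^ne x ne 0/1 matrix
  E <- as.matrix(do.call(expand.grid, rep(list(c(0, 1)), ne)))
  colnames(E) <- NULL
  w <- 2^(seq_len(ne) - 1)
  keys <- rep(Inf, nrow(E))
  for (k in seq_len(ncol(maps))) {
    keys <- pmin(keys, as.numeric(E[, maps[, k], drop = FALSE] %*% w))
  }
  reps <- which(!duplicated(keys))
  sum(vapply(reps, function(r) {
    oracle_connected(n, E[r, ] == 1, EP)
  }, logical(1)))
}

# random connected simple graph on n labelled nodes
random_connected_graph <- function(n) {
  EP <- t(utils::combn(n, 2L))
  repeat {
    sel <- stats::runif(nrow(EP)) < 0.5
    if (sum(sel) && oracle_connected(n, sel, EP)) {
      return(EP[sel, , drop = FALSE])
    }
  }
}
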