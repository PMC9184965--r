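# Rest points, unstable manifolds, basins, decision graphs.

test_that("cusp1d bistable landscape has exactly the expected rest points", {
  m <- landscape_model(make_family("cusp1d"), c(-1, 0))
  rp <- find_rest_points(m)
  expect_equal(nrow(rp), 3L)
  expect_equal(sort(rp$kind), c("attractor", "attractor", "saddle1"))
  atts <- rp[rp$kind == "attractor", ]
  expect_equal(sort(atts$x), c(-1, 1), tolerance = 1e-8)
  expect_equal(rp$x[rp$kind == "saddle1"], 0, tolerance = 1e-8)
  expect_lt(max(abs(sqrt(rowSums(
    eval_gradient(m$family, as.matrix(rp[, c("x", "y")]), m$theta)^2)))),
    1e-7)
})

test_that("rest-point set matches a dense-grid extremum oracle (box2)", {
  fam <- make_family("box2_example")
  m <- landscape_model(fam, numeric(0))
  rp <- find_rest_points(m)
  # oracle: local potential extrema / saddle pattern on a dense lattice
  n <- 400L
  xs <- seq(-4, 4, length.out = n)
  V <- outer(xs, xs, function(x, y) {
    eval_potential(fam, cbind(as.numeric(x), as.numeric(y)))
  })
  hits <- list()
  for (i in 2:(n - 1)) for (j in 2:(n - 1)) {
    nb <- c(V[i - 1, j], V[i + 1, j], V[i, j - 1], V[i, j + 1],
            V[i - 1, j - 1], V[i + 1, j + 1], V[i - 1, j + 1],
            V[i + 1, j - 1])
    below <- sum(nb < V[i, j])
    if (below == 0 || below == 8) {
      hits[[length(hits) + 1L]] <- c(xs[i], xs[j], below)
    }
  }
  # grid extrema: minima are attractors, maxima repellors; saddles found
  # separately through the gradient roots that are neither
  H <- do.call(rbind, hits)
  minima <- H[H[, 3] == 0, , drop = FALSE]
  expect_equal(nrow(minima), sum(rp$kind == "attractor"))
  atts <- rp[rp$kind == "attractor", ]
  for (k in seq_len(nrow(minima))) {
    d <- sqrt((atts$x - minima[k, 1])^2 + (atts$y - minima[k, 2])^2)
    expect_lt(min(d), 1e-1)  # lattice spacing limits the oracle
  }
  # Morse counting: attractors - saddles + repellors = 1
  expect_equal(sum(rp$kind == "attractor") - sum(rp$kind == "saddle1") +
                 sum(rp$kind == "repellor"), 1L)
})

test_that("dual cusp interior is tristable with two saddles", {
  m <- landscape_model(make_family("dual_cusp1d"), c(0.15, 0))
  rp <- find_rest_points(m)
  expect_equal(sum(rp$kind == "attractor"), 3L)
  expect_equal(sum(rp$kind == "saddle1"), 2L)
})

test_that("rest points and Morse indices are metric-invariant", {
  set.seed(31)
  fam <- make_family("box2_example")
  ref <- find_rest_points(landscape_model(fam, numeric(0)))
  for (i in 1:5) {
    m <- landscape_model(fam, numeric(0), riemannian_metric(random_spd()))
    rp <- find_rest_points(m)
    expect_equal(nrow(rp), nrow(ref))
    expect_equal(rp$x, ref$x, tolerance = 1e-7)
    expect_equal(rp$y, ref$y, tolerance = 1e-7)
    expect_equal(rp$morse_index, ref$morse_index)
    # flow-Jacobian inertia equals Hessian inertia for every SPD metric
    for (k in seq_len(nrow(rp))) {
      A <- -solve(eval_metric(m$metric, c(rp$x[k], rp$y[k])),
                  eval_hessian(fam, c(rp$x[k], rp$y[k]), numeric(0)))
      n_unstable <- sum(Re(eigen(A)$values) > 0)
      expect_equal(n_unstable, rp$morse_index[k])
    }
  }
})

test_that("cusp1d saddle branches reach the two attractors symmetrically", {
  m <- landscape_model(make_family("cusp1d"), c(-1, 0))
  rp <- find_rest_points(m)
  s <- rp$id[rp$kind == "saddle1"]
  br <- unstable_manifold(m, s, rest_points = rp)
  dests <- sort(vapply(br, function(b) {
    rp$x[match(b$destination, rp$id)]
  }, numeric(1)))
  expect_equal(dests, c(-1, 1), tolerance = 1e-3)
  # the two branches start antiparallel
  d1 <- br[[1]]$polyline[1, ]
  d2 <- br[[2]]$polyline[1, ]
  s_pos <- c(rp$x[match(s, rp$id)], rp$y[match(s, rp$id)])
  expect_equal(d1 - s_pos, -(d2 - s_pos), tolerance = 1e-10)
})

test_that("changing the Box 2 metric flips a saddle branch destination", {
  fam <- make_family("box2_example")
  mA <- landscape_model(fam, numeric(0), box2_metric_minus())
  mB <- landscape_model(fam, numeric(0), box2_metric_plus())
  rp <- find_rest_points(mA)
  flipped <- FALSE
  for (s in rp$id[rp$kind == "saddle1"]) {
    bA <- unstable_manifold(mA, s, rest_points = rp)
    bB <- unstable_manifold(mB, s, rest_points = rp)
    dA <- sort(vapply(bA, `[[`, "", "destination"))
    dB <- sort(vapply(bB, `[[`, "", "destination"))
    if (!identical(dA, dB)) flipped <- TRUE
  }
  expect_true(flipped)
})

test_that("basin assignment follows the 1D sign of the flow", {
  m <- landscape_model(make_family("cusp1d"), c(-1, 0))
  rp <- find_rest_points(m)
  id_plus <- rp$id[rp$kind == "attractor" & rp$x > 0]
  id_minus <- rp$id[rp$kind == "attractor" & rp$x < 0]
  expect_equal(basin_of(m, c(0.5, 0), rest_points = rp), id_plus)
  expect_equal(basin_of(m, c(-0.5, 0), rest_points = rp), id_minus)
  expect_equal(basin_of(m, c(1, 0), rest_points = rp), id_plus)
  expect_equal(basin_of(m, c(1e-9, 0), rest_points = rp), "undecidable")
})

test_that("grid basin fractions agree between two integration routes", {
  # dual-route check: adaptive lsodar integration (basin_of) against the
  # package's independent fixed-step relaxation, on a lattice
  m <- landscape_model(make_family("cusp1d"), c(-1, 0.2))
  rp <- find_rest_points(m)
  xs <- seq(-1.8, 1.8, length.out = 26)
  ys <- seq(-1.2, 1.2, length.out = 16)
  G <- as.matrix(expand.grid(xs, ys))
  ids <- apply(G, 1, function(x) basin_of(m, x, rest_points = rp))
  Xr <- fatescapes:::relax_population(m, G, m$theta, dt = 0.01,
                                      max_steps = 20000L)
  atts <- rp[rp$kind == "attractor", ]
  frac_route1 <- mean(ids == atts$id[which.max(atts$x)])
  d2 <- sapply(seq_len(nrow(atts)), function(k) {
    (Xr[, 1] - atts$x[k])^2 + (Xr[, 2] - atts$y[k])^2
  })
  frac_route2 <- mean(max.col(-d2) == which.max(atts$x))
  expect_lt(abs(frac_route1 - frac_route2), 0.02)
})

test_that("decision graphs collapse saddles into simple-graph edges", {
  m1 <- landscape_model(make_family("cusp1d"), c(-1, 0))
  g1 <- decision_graph(m1)
  expect_equal(length(g1$nodes), 2L)
  expect_equal(nrow(g1$edges), 1L)

  # the choice landscape: central progenitor adjacent to both peripheral
  # attractors, peripherals not adjacent (a path graph)
  m2 <- landscape_model(make_family("dual_cusp1d"), c(0.15, 0))
  g2 <- decision_graph(m2)
  expect_equal(length(g2$nodes), 3L)
  expect_equal(nrow(g2$edges), 2L)
  rp <- g2$rest_points
  central <- rp$id[rp$kind == "attractor" & abs(rp$x) < 0.1]
  expect_true(all(g2$edges$from == central | g2$edges$to == central))
  census <- enumerate_topologies(3)
  expect_equal(match_topology(g2, census)$label, "path")
})

test_that("deltoid interior carries an extra saddle-repellor pair", {
  m <- landscape_model(make_family("elliptic_umbilic"), c(0.02, 0))
  rp <- find_rest_points(m, grid_n = 24L, dedup_tol = 1e-6)
  expect_equal(sum(rp$kind == "attractor"), 3L)
  expect_equal(sum(rp$kind == "saddle1"), 3L)
  expect_equal(sum(rp$kind == "repellor"), 1L)
  g <- decision_graph(m, rest_points = rp)
  expect_true(all(g$edges$from %in% g$nodes & g$edges$to %in% g$nodes))
  expect_true(nrow(g$edges) <= choose(length(g$nodes), 2))
})

test_that("saddle branches terminate at attractors away from flips", {
  set.seed(32)
  m <- landscape_model(make_family("elliptic_umbilic"))
  n_br <- 0L; n_att <- 0L
  for (i in 1:12) {
    th <- stats::runif(2, -3, 3)
    rp <- tryCatch(find_rest_points(m, th), error = function(e) NULL)
    if (is.null(rp)) next
    for (s in rp$id[rp$kind == "saddle1"]) {
      br <- unstable_manifold(m, s, th, rest_points = rp)
      for (b in br) {
        n_br <- n_br + 1L
        if (b$destination %in% rp$id) n_att <- n_att + 1L
      }
    }
  }
  expect_gte(n_att / n_br, 0.99)
})

test_that("decision graph export formats are well-formed", {
  m <- landscape_model(make_family("dual_cusp1d"), c(0.15, 0))
  g <- decision_graph(m)
  fj <- tempfile(fileext = ".json")
  fd <- tempfile(fileext = ".dot")
  write_decision_graph(g, fj, "json")
  write_decision_graph(g, fd, "dot")
  back <- jsonlite::read_json(fj)
  expect_equal(length(back$nodes), 3L)
  expect_equal(length(back$edges), 2L)
  expect_true(any(grepl("--", readLines(fd))))
})
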