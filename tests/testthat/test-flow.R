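# Deterministic and stochastic time evolution.

test_that("vector field reduces to steepest descent under the identity", {
  fam <- make_family("cusp1d")
  m <- landscape_model(fam, c(-1, 0))
  x <- c(0.3, -0.2)
  expect_equal(vector_field(m, x), -eval_gradient(fam, x, c(-1, 0)))
  expect_equal(vector_field(m, c(1, 0)), c(0, 0))
})

test_that("Box 2 metric field matches the closed-form 2x2 inverse", {
  set.seed(21)
  fam <- make_family("box2_example")
  G <- matrix(c(1, -0.6, -0.6, 1), 2, 2)
  m <- landscape_model(fam, numeric(0), riemannian_metric(G))
  det_g <- 1 - 0.36
  for (i in 1:50) {
    x <- stats::runif(2, -3, 3)
    g <- eval_gradient(fam, x)
    v_oracle <- -c(g[1] - (-0.6) * g[2], -(-0.6) * g[1] + g[2]) / det_g
    expect_equal(vector_field(m, x), v_oracle, tolerance = 1e-12)
  }
})

test_that("trajectories from an attractor stay put", {
  fam <- make_family("cusp1d")
  m <- landscape_model(fam, c(-1, 0))
  tr <- integrate_flow(m, c(1, 0), t_end = 10)
  expect_lt(max(abs(tr$states[, 1] - 1)), 1e-6)
  expect_lt(max(abs(tr$states[, 2])), 1e-6)
})

test_that("bistable flow picks the attractor on its side of the saddle", {
  m <- landscape_model(make_family("cusp1d"), c(-1, 0))
  tr <- integrate_flow(m, c(0.1, 0), t_end = 200)
  expect_equal(tr$terminal_flag, "converged")
  expect_equal(unname(tr$states[nrow(tr$states), ]), c(1, 0),
               tolerance = 1e-5)
  tr2 <- integrate_flow(m, c(-0.1, 0), t_end = 200)
  expect_equal(unname(tr2$states[nrow(tr2$states), ]), c(-1, 0),
               tolerance = 1e-5)
})

test_that("potential is a Lyapunov function along deterministic flow", {
  set.seed(22)
  for (name in c("box2_example", "elliptic_umbilic")) {
    fam <- make_family(name)
    m <- landscape_model(fam, rep(0, fam$n_params))
    for (i in 1:20) {
      x0 <- stats::runif(2, -2, 2)
      tr <- integrate_flow(m, x0, t_end = 30)
      vals <- eval_potential(fam, tr$states, m$theta)
      expect_true(all(diff(vals) <= 1e-8))
    }
  }
})

test_that("zero-noise SDE agrees with a fixed-step deterministic solve", {
  fam <- make_family("cusp1d")
  m <- landscape_model(fam, c(-1, 0), sigma = 0)
  tr <- simulate_sde(m, c(0.3, 0.1), t_end = 5, dt = 1e-3, seed = 5,
                     record_every = 1000L)
  ref <- integrate_flow(m, c(0.3, 0.1), t_end = 5, n_out = 6L)
  expect_equal(unname(tr$states[nrow(tr$states), ]),
               unname(ref$states[nrow(ref$states), ]), tolerance = 1e-5)
})

test_that("identical seeds give bitwise-identical stochastic trajectories", {
  m <- landscape_model(make_family("cusp1d"), c(-1, 0), sigma = 0.3)
  t1 <- simulate_sde(m, c(1, 0), t_end = 2, dt = 1e-3, seed = 99)
  t2 <- simulate_sde(m, c(1, 0), t_end = 2, dt = 1e-3, seed = 99)
  expect_identical(t1$states, t2$states)
  t3 <- simulate_sde(m, c(1, 0), t_end = 2, dt = 1e-3, seed = 100)
  expect_false(identical(t3$states, t1$states))
  expect_error(simulate_sde(m, c(1, 0), t_end = 2, dt = -1, seed = 1), "dt")
})

test_that("moderate noise keeps a cell mostly in its starting basin", {
  # bistable cusp with barrier ~ 1/4 and sigma = 0.2: long-run occupancy
  # of the starting well stays above 90%
  m <- landscape_model(make_family("cusp1d"), c(-1, 0), sigma = 0.2)
  for (seed in 1:5) {
    tr <- simulate_sde(m, c(1, 0), t_end = 50, dt = 1e-3, seed = seed,
                       record_every = 10L)
    expect_gt(mean(tr$states[, 1] > 0), 0.9)
  }
})

test_that("trajectory export round-trips through CSV", {
  m <- landscape_model(make_family("cusp1d"), c(-1, 0))
  tr <- integrate_flow(m, c(0.4, 0.2), t_end = 3, n_out = 20L)
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  back <- utils::read.csv(f)
  expect_named(back, c("t", "x1", "x2", "theta1", "theta2"))
  expect_equal(back$x1, tr$states[, 1], tolerance = 1e-12)
})

test_that("compiled and R population kernels agree exactly when noiseless", {
  fam <- make_family("cusp1d")
  m <- landscape_model(fam, c(-1, 0), sigma = 0)
  X0 <- matrix(c(0.3, -0.4, 0.1, 0.2), 2, 2)
  p <- constant_path(c(-1, 0), 5)
  a <- fatescapes:::sde_population(m, X0, p, 5, 0.01)[[1]]
  fam_r <- fam; fam_r$cpp_id <- NULL
  m_r <- m; m_r$family <- fam_r
  b <- fatescapes:::sde_population(m_r, X0, p, 5, 0.01)[[1]]
  expect_equal(a, b, tolerance = 1e-14)
  ra <- fatescapes:::relax_population(m, X0, c(-1, 0), dt = 0.01)
  rb <- fatescapes:::relax_population(m_r, X0, c(-1, 0), dt = 0.01)
  expect_equal(ra, rb, tolerance = 1e-10)
})
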