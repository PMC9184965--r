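# Likelihood-free fitting machinery.

toy_table <- function(p, fates = c("A", "B")) {
  fatescapes:::new_fate_table(
    data.frame(condition = "c", time = 1, fate = fates,
               count = round(100 * p), proportion = p))
}

test_that("fate distance is a symmetric mean absolute difference", {
  a <- toy_table(c(1, 0))
  b <- toy_table(c(0, 1))
  expect_equal(fate_distance(a, a), 0)
  expect_equal(fate_distance(a, b), 1)
  expect_equal(fate_distance(a, b), fate_distance(b, a))
  c_ <- toy_table(c(0.6, 0.4))
  expect_equal(fate_distance(a, c_), mean(c(0.4, 0.4)))
  bad <- toy_table(c(0.5, 0.5), fates = c("A", "C"))
  expect_error(fate_distance(a, bad), "missing keys.*C")
})

# toy simulator: two-fate table whose proportion responds linearly to
# theta, with binomial sampling noise -- fast and analytically transparent
toy_simulator <- function(n_obs = 200L) {
  function(theta, seed) {
    p <- stats::plogis(2 * theta[1] + theta[2])
    k <- fatescapes:::with_seed(seed, stats::rbinom(1, n_obs, p))
    toy_table(c(k, n_obs - k) / n_obs)
  }
}

test_that("a single prior generation reproduces the prior", {
  sim <- toy_simulator()
  obs <- toy_table(c(0.5, 0.5))
  priors <- prior_spec(c(-1, -2), c(1, 2))
  post <- abc_smc(sim, obs, priors, n_particles = 400L,
                  n_generations = 1L, seed = 7)
  expect_equal(post$epsilon_history, Inf)
  for (j in 1:2) {
    ks <- stats::ks.test(post$particles[, j],
                         "punif", priors$lower[j], priors$upper[j])
    expect_lt(unname(ks$statistic), 0.1)
  }
})

test_that("ABC-SMC is deterministic under a fixed seed and concentrates", {
  sim <- toy_simulator()
  true_theta <- c(0.3, -0.5)
  obs <- fatescapes:::with_seed(99, {
    p <- stats::plogis(2 * true_theta[1] + true_theta[2])
    toy_table(c(p, 1 - p))
  })
  priors <- prior_spec(c(-1, -2), c(1, 2))
  p1 <- abc_smc(sim, obs, priors, n_particles = 100L, n_generations = 3L,
                seed = 11)
  p2 <- abc_smc(sim, obs, priors, n_particles = 100L, n_generations = 3L,
                seed = 11)
  expect_identical(p1$particles, p2$particles)
  expect_identical(p1$weights, p2$weights)
  # tolerances decrease and the posterior variance shrinks
  eh <- p1$epsilon_history[is.finite(p1$epsilon_history)]
  expect_true(all(diff(eh) <= 0))
  v0 <- (priors$upper - priors$lower)^2 / 12
  vT <- fatescapes:::wtd_var(p1$particles, p1$weights)
  expect_true(all(vT <= v0))
})

test_that("posterior summaries match hand computations", {
  # single particle with weight one
  post1 <- structure(list(particles = matrix(2.5, 1, 1,
                                             dimnames = list(NULL, "a")),
                          weights = 1, distances = 0,
                          epsilon_history = Inf, acceptance_rates = 1,
                          status = "ok", seed = 1L),
                     class = "abc_posterior")
  s1 <- posterior_summary(post1)
  expect_equal(s1$mean, 2.5)
  expect_equal(s1$variance, 0)

  # equal weights on a grid: mean at the centroid
  grid <- as.matrix(expand.grid(a = 1:3, b = c(0, 10)))
  post2 <- structure(list(particles = grid,
                          weights = rep(1 / 6, 6), distances = rep(0, 6),
                          epsilon_history = Inf, acceptance_rates = 1,
                          status = "ok", seed = 1L),
                     class = "abc_posterior")
  s2 <- posterior_summary(post2)
  expect_equal(s2$mean, c(2, 5))

  # effective sample size 1 / sum(w^2) for hand-picked weights
  w <- c(0.5, 0.3, 0.2)
  post3 <- structure(list(particles = matrix(1:3, 3, 1,
                                             dimnames = list(NULL, "a")),
                          weights = w, distances = rep(0, 3),
                          epsilon_history = Inf, acceptance_rates = 1,
                          status = "ok", seed = 1L),
                     class = "abc_posterior")
  expect_equal(attr(posterior_summary(post3), "ess"),
               1 / (0.25 + 0.09 + 0.04))
})

test_that("toy posterior recovers the generating parameter combination", {
  sim <- toy_simulator(500L)
  true_theta <- c(0.4, 0)
  p_true <- stats::plogis(2 * true_theta[1] + true_theta[2])
  obs <- toy_table(c(p_true, 1 - p_true))
  priors <- prior_spec(c(-1, -0.001), c(1, 0.001))  # second param pinned
  post <- abc_smc(sim, obs, priors, n_particles = 150L,
                  n_generations = 4L, seed = 21)
  s <- posterior_summary(post)
  expect_lt(abs(s$mean[1] - true_theta[1]), 0.2)
})

test_that("posterior export writes particles and run metadata", {
  sim <- toy_simulator()
  obs <- toy_table(c(0.5, 0.5))
  priors <- prior_spec(c(-1, -1), c(1, 1), c("p1", "p2"))
  post <- abc_smc(sim, obs, priors, n_particles = 60L,
                  n_generations = 2L, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_posterior(post, f)
  back <- utils::read.csv(f)
  expect_named(back, c("p1", "p2", "weight", "distance"))
  md <- jsonlite::read_json(paste0(f, ".meta.json"))
  expect_equal(md$seed, 3L)
  expect_equal(md$status, "ok")
})
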