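# Population simulation, fate tables, synthetic datasets.

test_that("fate table proportions are consistent and normalized", {
  m <- eu_flip_model()
  sch <- eu_flip_schedule(50, b_off = 0.1)
  tab <- simulate_population(m, sch, seed = 3)
  d <- as.data.frame(tab)
  for (t in unique(d$time)) {
    expect_equal(sum(d$count[d$time == t]), 50L)
    expect_equal(sum(d$proportion[d$time == t]), 1, tolerance = 1e-12)
  }
})

test_that("zero cells give an empty table with a valid schema", {
  m <- eu_flip_model()
  sch <- eu_flip_schedule(0)
  tab <- simulate_population(m, sch, seed = 1)
  expect_equal(nrow(tab), 0L)
  expect_named(as.data.frame(tab),
               c("condition", "time", "fate", "count", "proportion"))
})

test_that("fate_proportions renormalizes and is idempotent", {
  df <- data.frame(condition = "c", time = 1,
                   fate = c("A", "B", "undecided"),
                   count = c(30L, 60L, 10L),
                   proportion = c(0.3, 0.6, 0.1))
  tab <- fatescapes:::new_fate_table(df)
  p1 <- fate_proportions(tab)
  expect_equal(p1$proportion, c(0.3, 0.6, 0.1))
  p2 <- fate_proportions(tab, drop_undecided = TRUE)
  expect_equal(p2$proportion, c(1 / 3, 2 / 3))
  expect_equal(fate_proportions(p2, drop_undecided = TRUE)$proportion,
               p2$proportion)
  bad <- fatescapes:::new_fate_table(
    data.frame(condition = "c", time = 1, fate = "undecided",
               count = 5L, proportion = 1))
  expect_error(fate_proportions(bad, drop_undecided = TRUE), "undefined")
})

test_that("crossing the fold sends nearly all cells to the survivor", {
  # cusp path destroying the occupied attractor at x = -1
  fam <- make_family("cusp1d")
  m <- landscape_model(fam, c(-1, 0), sigma = 0.01)
  path <- signal_path(c(0, 4, 10), cbind(c(-1, -1, -1), c(0, -0.6, -0.6)))
  refs <- list(minus = c(-1, 0), plus = c(1, 0))
  sch <- signal_schedule(list(pulse = path), t_obs = 10, n_cells = 200,
                         x0 = list(point = c(-1, 0), sd = 0.02),
                         fate_refs = refs, dt = 0.01)
  tab <- simulate_population(m, sch, seed = 8)
  d <- as.data.frame(tab)
  expect_gte(d$proportion[d$fate == "plus"], 0.99)
})

test_that("symmetric flip ramp splits committed fates near 50/50", {
  m <- eu_flip_model()
  sch <- eu_flip_schedule(200)
  props <- vapply(1:3, function(seed) {
    d <- as.data.frame(simulate_population(m, sch, seed = seed))
    d$proportion[d$fate == "A"]
  }, numeric(1))
  se <- sqrt(0.25 / 200)
  expect_true(all(abs(props - 0.5) < 4 * se))
})

test_that("proportions are stable under doubling of the population", {
  m <- eu_flip_model()
  p_small <- vapply(1:3, function(s) {
    d <- as.data.frame(simulate_population(m, eu_flip_schedule(100,
                                                               b_off = 0.1),
                                           seed = s))
    d$proportion[d$fate == "A"]
  }, numeric(1))
  p_big <- vapply(1:3, function(s) {
    d <- as.data.frame(simulate_population(m, eu_flip_schedule(200,
                                                               b_off = 0.1),
                                           seed = 10 + s))
    d$proportion[d$fate == "A"]
  }, numeric(1))
  se <- sqrt(mean(p_small) * (1 - mean(p_small)) / 100)
  expect_lt(abs(mean(p_small) - mean(p_big)), 3 * se)
})

test_that("synthetic datasets are seed-deterministic and converge in n", {
  m <- eu_flip_model()
  sch <- eu_flip_schedule(150, b_off = 0.1)
  d1 <- synth_dataset(m, sch, seed = 5, multinomial_n = 100)
  d2 <- synth_dataset(m, sch, seed = 5, multinomial_n = 100)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  # large multinomial size recovers the simulated proportions
  base <- simulate_population(m, sch, seed = 5)
  dbig <- synth_dataset(m, sch, seed = 5, multinomial_n = 1e5)
  expect_lt(max(abs(as.data.frame(dbig)$proportion -
                      as.data.frame(base)$proportion)), 0.01)
  expect_error(synth_dataset(m, sch, seed = 1, multinomial_n = 0),
               "multinomial_n")
})

test_that("fate tables round-trip through CSV with metadata sidecar", {
  m <- eu_flip_model()
  tab <- synth_dataset(m, eu_flip_schedule(50), seed = 2,
                       multinomial_n = 80, true_params = c(a = -6, b = 0))
  f <- tempfile(fileext = ".csv")
  write_fate_table(tab, f)
  back <- read_fate_table(f)
  for (col in names(back)) {
    expect_equal(back[[col]], tab[[col]], info = col)
  }
  md <- attr(back, "metadata")
  expect_equal(md$seed, 2L)
  expect_equal(md$multinomial_n, 80L)
  expect_equal(unlist(md$true_params), c(a = -6, b = 0))
})

test_that("split_fate_table partitions by condition", {
  df <- data.frame(condition = rep(c("c1", "c2"), each = 2), time = 1,
                   fate = c("A", "B"), count = 1L, proportion = 0.5)
  tab <- fatescapes:::new_fate_table(df)
  sp <- split_fate_table(tab, "c1")
  expect_equal(unique(sp$selected$condition), "c1")
  expect_equal(unique(sp$rest$condition), "c2")
})

test_that("committed-fate split shifts monotonically with path offset", {
  m <- eu_flip_model()
  offs <- c(0, 0.08, 0.16, 0.24)
  mean_props <- vapply(offs, function(b) {
    mean(vapply(1:3, function(s) {
      d <- as.data.frame(simulate_population(m, eu_flip_schedule(150,
                                                                 b_off = b),
                                             seed = s))
      d$proportion[d$fate == "A"]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_props) < 0))
  expect_gt(mean_props[1] - mean_props[length(offs)], 0.2)
})
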