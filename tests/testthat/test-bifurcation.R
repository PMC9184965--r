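# Fold continuation, cusps, flips, and the atlas.

test_that("fold residual vanishes exactly at a double root", {
  fam <- make_family("cusp1d")
  # x^3 - 3x + 2 = (x - 1)^2 (x + 2): double root at x = 1
  r <- fold_residual(fam, c(1, 0), c(-3, 2))
  expect_equal(unname(r), c(0, 0), tolerance = 1e-12)
  # the simple root at x = -2 is a regular rest point, not a fold
  r2 <- fold_residual(fam, c(-2, 0), c(-3, 2))
  expect_lt(r2[["grad_norm"]], 1e-12)
  expect_gt(abs(r2[["det_hess"]]), 1)
})

test_that("traced cusp fold curve lies on the cubic discriminant locus", {
  fam <- make_family("cusp1d")
  cv <- trace_fold_curve(fam, list(x = c(1, 0), theta = c(-3, 2)))
  expect_gt(nrow(cv$points), 100)
  disc <- 4 * cv$points[, 1]^3 + 27 * cv$points[, 2]^2
  expect_lt(max(abs(disc)), 1e-5)
  # the seed point itself lies on the curve
  d <- sqrt((cv$points[, 1] + 3)^2 + (cv$points[, 2] - 2)^2)
  expect_lt(min(d), 1e-6)
  # residuals along the curve are tiny
  for (i in seq(1, nrow(cv$points), length.out = 12)) {
    r <- fold_residual(fam, cv$states[i, ], cv$points[i, ])
    expect_lt(r[["grad_norm"]], 1e-7)
    expect_lt(abs(r[["det_hess"]]), 1e-7)
  }
  expect_error(trace_fold_curve(fam, list(x = c(5, 5), theta = c(1, 1))),
               "seed")
})

test_that("cusp detection refines to the origin and classifies standard", {
  fam <- make_family("cusp1d")
  cv <- trace_fold_curve(fam, list(x = c(1, 0), theta = c(-3, 2)))
  cp <- detect_cusps(cv, fam)
  expect_equal(nrow(cp), 1L)
  expect_lt(abs(cp$a), 1e-6)
  expect_lt(abs(cp$b), 1e-6)
  expect_equal(cp$kind, "standard")
  expect_equal(cp$n_attr_inside, 2L)
  expect_equal(cp$n_attr_outside, 1L)
})

test_that("dual-cusp family shows a dual cusp with tristable interior", {
  fam <- make_family("dual_cusp1d")
  # seed on the central fold branch (double root of the quintic)
  x <- 0.228
  cv <- trace_fold_curve(fam, list(x = c(x, 0),
                                   theta = c(3 * x^2 - 5 * x^4,
                                             4 * x^5 - 2 * x^3)),
                         step = 0.01)
  cp <- detect_cusps(cv, fam)
  duals <- cp[cp$kind %in% "dual", , drop = FALSE]
  expect_gte(nrow(duals), 1L)
  expect_true(any(duals$n_attr_inside == 3 & duals$n_attr_outside == 2))
})

test_that("cusp classification is stable under probe re-draws", {
  fam <- make_family("cusp1d")
  cv <- trace_fold_curve(fam, list(x = c(1, 0), theta = c(-3, 2)))
  set.seed(41)
  kinds <- vapply(1:10, function(i) {
    detect_cusps(cv, fam, probe_delta = 0.08 * stats::runif(1, 0.6, 1.6))$kind[1]
  }, character(1))
  expect_true(all(kinds == "standard"))
})

test_that("elliptic umbilic hosts a deltoid fold loop with three cusps", {
  fam <- make_family("elliptic_umbilic")
  cv <- trace_fold_curve(fam, list(x = c(0.18, 0), theta = c(0.051, 0)),
                         step = 0.002, max_steps = 400L)
  expect_true(cv$closed)
  cp <- detect_cusps(cv, fam)
  expect_equal(nrow(cp), 3L)
  # a vertical line through the loop crosses the fold set at least twice,
  # and the three-cusped loop encloses an interior component
  a_mid <- mean(range(cv$points[, 1]))
  crossings <- sum(abs(diff(sign(cv$points[, 1] - a_mid))) > 0)
  expect_gte(crossings, 2L)
})

test_that("symmetry pins the elliptic-umbilic flip to b = 0", {
  m <- landscape_model(make_family("elliptic_umbilic"))
  fl <- locate_flip(m, c(-1, -0.5), c(-1, 0.5), c(-0.49, 0), tol = 1e-6)
  expect_lt(abs(fl$theta_star[2]), 1e-6)
  # at the critical parameter the branch passes close to the sink saddle
  expect_lt(fl$approach_dist, 1e-3)
  expect_false(fl$dest0 == fl$dest1)
})

test_that("locate_flip raises the documented errors", {
  m <- landscape_model(make_family("elliptic_umbilic"))
  expect_error(locate_flip(m, c(-1, 0.2), c(-1, 0.5), c(-0.49, 0)),
               "no flip")
})

test_that("flip curve follows the symmetry axis and self-checks", {
  m <- landscape_model(make_family("elliptic_umbilic"))
  fl <- locate_flip(m, c(-1, -0.3), c(-1, 0.3), c(-0.49, 0), tol = 1e-5)
  cv <- trace_flip_curve(m, fl, box = list(lower = c(-2, -1),
                                           upper = c(-0.5, 1)),
                         step = 0.12, tol = 1e-5, max_steps = 20L)
  expect_gte(nrow(cv$points), 8L)
  expect_lt(max(abs(cv$points[, 2])), 1e-3)
  # closest-approach invariant at a sample of points
  for (i in round(seq(1, nrow(cv$points), length.out = 4))) {
    fl_i <- locate_flip(m, cv$points[i, ] + c(0, -0.05),
                        cv$points[i, ] + c(0, 0.05),
                        cv$source_pts[i, ], tol = 1e-6)
    expect_lt(fl_i$approach_dist, 1e-3)
  }
})

test_that("cusp1d atlas has a bistable wedge inside the fold set", {
  atlas <- build_atlas(make_family("cusp1d"))
  expect_equal(length(atlas$fold_curves), 1L)
  expect_equal(length(atlas$flip_curves), 0L)
  archs <- vapply(atlas$regions, `[[`, "", "archetype")
  counts <- vapply(atlas$regions, `[[`, 1L, "n_attractors")
  expect_setequal(archs, c("monostable", "bistable"))
  # attractor counts change by one across the fold curve
  expect_setequal(counts, c(1L, 2L))
  expect_equal(mechanism_types(atlas), "rest_point_collision")
})

test_that("dual-cusp tristable region is labelled binary_choice", {
  # zoomed box: the tristable wedge is narrow in the b direction
  atlas <- build_atlas(make_family("dual_cusp1d"),
                       box = list(lower = c(-0.1, -0.1),
                                  upper = c(0.6, 0.1)),
                       resolution = 22L, fold_step = 0.01)
  archs <- vapply(atlas$regions, `[[`, "", "archetype")
  expect_true("binary_choice" %in% archs)
  tri <- atlas$regions[[which(archs == "binary_choice")[1]]]
  expect_equal(tri$n_attractors, 3L)
})

test_that("atlas export is valid JSON with labelled components", {
  atlas <- build_atlas(make_family("cusp1d"))
  f <- tempfile(fileext = ".json")
  write_atlas(atlas, f)
  back <- jsonlite::read_json(f)
  expect_equal(length(back$fold_curves), 1L)
  expect_true(all(vapply(back$regions, function(r) {
    r$archetype %in% c("monostable", "bistable")
  }, logical(1))))
})
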