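test_that("error_norm handles identity, constant offsets and alternating differences", {
  g <- seq(0, 1, length.out = 101)
  a <- fes_curve(g, sin(2 * pi * g) * 10)
  expect_equal(error_norm(a, a)$norm, 0)
  expect_equal(error_norm(a, a)$per_point, 0)
  b <- fes_curve(g, a$F + 7)
  expect_equal(error_norm(a, b, alignment = "mean")$norm, 0, tolerance = 1e-10)
  en <- error_norm(a, b, alignment = "none")
  expect_equal(en$norm, sqrt(100 * 49), tolerance = 1e-10) # 7 per point at n=100
  expect_equal(en$per_point, 0.7, tolerance = 1e-10)
  # +/-1 alternating, zero mean: norm 10, per-point 0.1
  g2 <- seq(0, 1, length.out = 100)
  c1 <- fes_curve(g2, rep(0, 100))
  c2 <- fes_curve(g2, rep(c(1, -1), 50))
  en2 <- error_norm(c1, c2, alignment = "mean")
  expect_equal(en2$norm, 10, tolerance = 1e-9)
  expect_equal(en2$per_point, 0.1, tolerance = 1e-9)
})

test_that("aligned error_norm is a pseudo-metric on a fixed grid", {
  set.seed(61)
  g <- seq(0.2, 1.0, length.out = 100)
  curves <- lapply(1:3, function(i) fes_curve(g, cumsum(rnorm(100))))
  en <- function(a, b) error_norm(a, b)$norm
  expect_equal(en(curves[[1]], curves[[2]]), en(curves[[2]], curves[[1]]))
  expect_lte(en(curves[[1]], curves[[3]]),
             en(curves[[1]], curves[[2]]) + en(curves[[2]], curves[[3]]) + 1e-9)
})

test_that("disjoint spans are rejected", {
  a <- fes_curve(seq(0, 0.4, length.out = 10), rnorm(10))
  b <- fes_curve(seq(0.5, 1, length.out = 10), rnorm(10))
  expect_error(error_norm(a, b), "disjoint")
})

test_that("landmarks of the synthetic truth curve sit at the designed positions", {
  pot <- make_potential("mgcl")
  g <- seq(0.206, 0.99, length.out = 785)
  truth <- fes_curve(g, evaluate_potential(pot, g)$energy)
  lk <- locate_landmarks(truth)
  expect_true(lk$complete)
  expect_equal(lk$cip_s, 0.23, tolerance = 1e-3)
  expect_equal(lk$ssip_s, 0.47, tolerance = 1e-3)
  expect_true(lk$barrier_s > lk$cip_s && lk$barrier_s < lk$ssip_s)
  expect_equal(lk$ssip_minus_cip, 20, tolerance = 0.01)
  expect_equal(lk$barrier_from_ssip, 30, tolerance = 0.01)
  # stability under 2x grid refinement
  g2 <- seq(0.206, 0.99, length.out = 1569)
  lk2 <- locate_landmarks(fes_curve(g2, evaluate_potential(pot, g2)$energy))
  expect_lt(abs(lk2$cip_s - lk$cip_s), 0.002)
  expect_lt(abs(lk2$barrier_s - lk$barrier_s), 0.002)
})

test_that("a single-well curve yields a partial landmark report", {
  g <- seq(0, 1, length.out = 101)
  lk <- locate_landmarks(fes_curve(g, 50 * (g - 0.5)^2))
  expect_false(lk$complete)
  expect_equal(lk$cip_s, 0.5, tolerance = 1e-6)
  expect_true(is.na(lk$ssip_s))
  expect_true(is.na(lk$barrier_s))
})

test_that("mirroring a curve relabels the minima consistently", {
  pot <- make_potential("mgcl")
  g <- seq(0.206, 0.99, length.out = 785)
  v <- evaluate_potential(pot, g)$energy
  lk <- locate_landmarks(fes_curve(g, v))
  mirrored <- fes_curve(g, rev(v))
  lkm <- locate_landmarks(mirrored)
  # the deep CIP well is now on the right; labels follow position
  expect_equal(lkm$cip_s, min(g) + max(g) - lk$ssip_s, tolerance = 1e-6)
  expect_equal(lkm$ssip_s, min(g) + max(g) - lk$cip_s, tolerance = 1e-6)
  expect_equal(lkm$ssip_minus_cip, -lk$ssip_minus_cip, tolerance = 1e-6)
})

test_that("noise wiggles below the prominence threshold are ignored", {
  g <- seq(0.2, 1.0, length.out = 400)
  pot <- make_potential("mgcl")
  set.seed(62)
  v <- evaluate_potential(pot, g)$energy + 0.4 * sin(g * 300) # sub-kJ ripples
  lk <- locate_landmarks(fes_curve(g, v))
  # the ripple genuinely shifts the vertices by up to |ripple'|/curvature
  expect_lt(abs(lk$cip_s - 0.23), 0.01)
  expect_lt(abs(lk$ssip_s - 0.47), 0.01)
  expect_length(lk$minima_s, 2L)
})

test_that("a degenerate single-cell sweep produces one record per training set", {
  set.seed(63)
  pot <- make_potential("mgcl")
  s <- sort(runif(300, 0.25, 0.95))
  tr <- training_set(s, evaluate_potential(pot, s)$gradient)
  g <- seq(0.206, 0.99, length.out = 100)
  ref <- fes_curve(g, evaluate_potential(pot, g)$energy)
  sw <- run_sweep(list(a = tr, b = tr), ref, deltas = 0.65, sigmas = 0.1,
                  thetas = 0.25)
  expect_equal(nrow(sw), 2L)
  expect_false(any(sw$failed))
  expect_equal(sw$error_per_point, sw$error_norm / 100)
  # identical inputs give identical records (sweep determinism)
  sw2 <- run_sweep(list(a = tr, b = tr), ref, deltas = 0.65, sigmas = 0.1,
                   thetas = 0.25)
  expect_identical(sw, sw2)
})

test_that("sweep summaries list tied best rows in (delta, sigma, theta) order", {
  rec <- data.frame(subset = "a", mode = "dense", grid_size = NA_integer_,
                    delta = c(0.9, 0.4, 0.65), sigma = 0.1,
                    theta = c(0.25, 0.25, 0.3),
                    error_norm = c(5, 5, 7), error_per_point = c(5, 5, 7) / 100,
                    failed = FALSE)
  class(rec) <- c("sweep_records", "data.frame")
  am <- sweep_argmin(rec)
  expect_equal(nrow(am), 2L)
  expect_equal(am$delta, c(0.4, 0.9))
  sm <- summarize_sweep(rec)
  # one |sigma| x |theta| matrix per delta present in the group
  expect_length(sm$heatmaps, 3L)
  expect_equal(dim(sm$heatmaps[[1]]), c(1L, 1L))
  expect_true(any(grepl("best rows", sm$lines)))
})
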