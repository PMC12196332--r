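test_that("window construction spans the range inclusively with uniform spacing", {
  w <- make_windows()
  expect_equal(nrow(w), 49L)
  expect_equal(w$center[1], 0.206)
  expect_equal(w$center[49], 0.99)
  expect_equal(unique(round(diff(w$center), 12)), round((0.99 - 0.206) / 48, 12))
  w2 <- make_windows(c(0.3, 0.5), n_windows = 2)
  expect_equal(w2$center, c(0.3, 0.5))
  expect_true(all(diff(make_windows(n_windows = 17)$center) > 0))
  expect_error(make_windows(c(0.5, 0.5)), "degenerate")
})

test_that("a single unrestrained window reduces WHAM to -kT ln(histogram)", {
  set.seed(51)
  samp <- rnorm(20000, 0.6, 0.05)
  win <- umbrella_window(center = 0.6, spring_k = 1e-12, samples = samp)
  edges <- seq(0.4, 0.8, by = 0.01)
  res <- wham_solve(list(win), bin_edges = edges, tol = 1e-10)
  counts <- tabulate(findInterval(samp, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  keep <- counts > 0
  direct <- -kT300 * log(counts[keep] / sum(counts) / 0.01)
  expect_equal(res$fes$F, direct - min(direct), tolerance = 1e-6)
})

test_that("two exactly-sampled overlapping windows recover a harmonic free energy", {
  # F(s) = (a/2)(s - c0)^2; biased density of window i is Gaussian with
  # stiffness a + k, mean at the weighted average of c0 and the window center
  a <- 800; c0 <- 0.5; k <- 1500
  centers <- c(0.45, 0.55)
  n <- 4e5
  wins <- list()
  set.seed(52)
  for (i in 1:2) {
    prec <- a + k
    mu <- (a * c0 + k * centers[i]) / prec
    wins[[i]] <- umbrella_window(centers[i], k,
                                 rnorm(n, mu, sqrt(kT300 / prec)))
  }
  edges <- seq(0.35, 0.65, by = 0.002)
  res <- wham_solve(wins, bin_edges = edges, tol = 1e-10)
  truth <- (a / 2) * (res$fes$s - c0)^2
  d <- res$fes$F - (truth - min(truth))
  d <- d - mean(d)
  # compare only where sampling is meaningful
  csum <- colSums(res$counts)
  ok <- csum[csum > 0] > 500 # aligned with res$fes rows
  expect_lt(sqrt(mean(d[ok]^2)), 0.2)
})

test_that("a very stiff spring pins the window at its center with variance kT/k", {
  pot <- make_potential("mgcl")
  th <- thermo_state(seed = 53)
  w <- data.frame(center = 0.6, spring_k = 1e7)
  sw <- sample_windows(pot, w, th, n_steps = 2e5, stride = 10, n_equil = 1e4)
  s <- sw[[1]]$samples
  expect_equal(var(s), kT300 / 1e7, tolerance = 0.15)
  expect_lt(abs(mean(s) - 0.6), 3 * sqrt(kT300 / 1e7))
})

test_that("window sampling is deterministic in the base seed", {
  pot <- make_potential("mgcl")
  th <- thermo_state(seed = 54)
  w <- make_windows(n_windows = 3)
  a <- sample_windows(pot, w, th, n_steps = 2e4, stride = 100, n_equil = 1e3)
  b <- sample_windows(pot, w, th, n_steps = 2e4, stride = 100, n_equil = 1e3)
  expect_identical(lapply(a, `[[`, "samples"), lapply(b, `[[`, "samples"))
})

test_that("converged WHAM satisfies both self-consistent equations and is a fixed point", {
  pot <- make_potential("mgcl")
  th <- thermo_state(seed = 55)
  w <- make_windows(c(0.4, 0.56), n_windows = 9, spring_k = 5000)
  sw <- sample_windows(pot, w, th, n_steps = 2e5, stride = 100, n_equil = 2e4)
  edges <- seq(0.38, 0.58, by = 0.002)
  res <- wham_solve(sw, bin_edges = edges, tol = 1e-10)
  expect_true(res$converged)
  # verify the equations directly from the reported P and f
  mid <- res$bin_centers; db <- diff(edges)
  P_full <- res$prob
  N <- rowSums(res$counts)
  wmat <- outer(w$center, mid, function(c, s) 0.5 * 5000 * (s - c)^2)
  E <- exp(-wmat / kT300)
  f_direct <- -kT300 * log(as.numeric(E %*% (P_full * db)))
  f_direct <- f_direct - f_direct[1]
  expect_equal(res$window_free_energies, f_direct, tolerance = 1e-8)
  z <- exp((f_direct - f_direct[1]) / kT300)
  # P equation: P_j  proportional to counts / sum_i N_i z_i E_ij (same gauge)
  denom <- as.numeric(crossprod(E, N * exp(f_direct / kT300)))
  P_eq <- colSums(res$counts) / denom
  P_eq <- P_eq / sum(P_eq * db)
  expect_equal(P_full, P_eq, tolerance = 1e-7)
  # doubling max_iter changes nothing once converged
  res2 <- wham_solve(sw, bin_edges = edges, tol = 1e-10, max_iter = 2e6)
  expect_equal(res$fes$F, res2$fes$F)
})

test_that("WHAM output is invariant to the gauge and stable under bin refinement", {
  pot <- make_potential("mgcl")
  th <- thermo_state(seed = 56)
  w <- make_windows(c(0.3, 0.55), n_windows = 14, spring_k = 5000)
  sw <- sample_windows(pot, w, th, n_steps = 2e5, stride = 100, n_equil = 2e4)
  coarse <- wham_solve(sw, bin_edges = seq(0.28, 0.57, by = 0.004))
  fine <- wham_solve(sw, bin_edges = seq(0.28, 0.57, by = 0.002))
  lm_c <- locate_landmarks(coarse$fes)
  lm_f <- locate_landmarks(fine$fes)
  expect_lt(abs(lm_c$cip_s - lm_f$cip_s), 0.004)
  expect_equal(coarse$window_free_energies[1], 0)
})

test_that("non-overlapping windows are rejected with the disconnected span named", {
  set.seed(57)
  w1 <- umbrella_window(0.3, 5000, rnorm(1000, 0.3, 0.01))
  w2 <- umbrella_window(0.9, 5000, rnorm(1000, 0.9, 0.01))
  expect_error(wham_solve(list(w1, w2), bin_edges = seq(0.25, 0.95, by = 0.002)),
               "non-overlapping windows.*0\\.3.*0\\.9")
})
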