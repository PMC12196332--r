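test_that("bias of an empty log is zero and single-hill values follow the closed form", {
  empty <- hills_log()
  expect_equal(bias_value(empty, c(0.1, 0.5, 2)), c(0, 0, 0))
  one <- hills_log(time = 1, center = 0.3, height = 0.8, width = 0.01,
                   bias_factor = 20, omega0 = 0.8)
  expect_equal(bias_value(one, 0.3), 0.8)
  expect_equal(bias_value(one, 0.31), 0.8 * exp(-0.5))
  # gradient: zero at the center, closed form one width away
  expect_equal(bias_gradient(one, 0.3), 0)
  expect_equal(bias_gradient(one, 0.3 + 0.01), -(0.8 / 0.01) * exp(-0.5))
})

test_that("vectorized hill sums equal a naive per-hill loop for 1000 random hills", {
  set.seed(11)
  n <- 1000
  log <- hills_log(time = sort(runif(n, 0, 100)) + seq_len(n) * 1e-6,
                   center = runif(n, 0.2, 1.0),
                   height = runif(n, 0.05, 0.8),
                   width = 0.01, bias_factor = 20, omega0 = 0.8)
  s <- runif(50, 0.2, 1.0)
  expect_equal(bias_value(log, s), naive_hill_sum(log, s), tolerance = 1e-10)
  expect_equal(bias_gradient(log, s), naive_hill_sum(log, s, deriv = TRUE),
               tolerance = 1e-10)
  # causal cutoff agrees too
  tc <- 50
  expect_equal(bias_value(log, s, t_cutoff = tc),
               naive_hill_sum(log, s, t_cutoff = tc), tolerance = 1e-10)
})

test_that("bias gradients match central differences of the bias", {
  set.seed(12)
  log <- hills_log(time = 1:200, center = runif(200, 0.3, 0.7),
                   height = runif(200, 0.1, 0.8), width = 0.01,
                   bias_factor = 20, omega0 = 0.8)
  s <- runif(20, 0.3, 0.7)
  fd <- fd_grad(function(x) bias_value(log, x), s, h = 1e-7)
  expect_equal(bias_gradient(log, s), fd, tolerance = 1e-4)
})

test_that("bias is non-negative and non-decreasing in the time cutoff", {
  set.seed(13)
  log <- hills_log(time = 1:300, center = runif(300, 0.25, 0.95),
                   height = runif(300, 0.1, 0.8), width = 0.01,
                   bias_factor = 20, omega0 = 0.8)
  s <- seq(0.25, 0.95, by = 0.05)
  prev <- numeric(length(s))
  for (tc in c(10, 50, 100, 200, 300)) {
    cur <- bias_value(log, s, t_cutoff = tc)
    expect_true(all(cur >= prev - 1e-12))
    prev <- cur
  }
})

test_that("tempered deposition follows omega0 * exp(-V / kB dT) exactly", {
  # first-ever hill has height omega0
  log <- hills_log(width = 0.01, bias_factor = 20, omega0 = 0.8)
  log <- deposit_hill(log, 0.3, 1)
  expect_equal(log$hills$height[1], 0.8)
  # accumulated bias of kB*dT*ln(2) at the deposition point halves the height
  kdT <- kB * 19 * 300
  log2 <- hills_log(time = 1, center = 0.3, height = kdT * log(2), width = 0.01,
                    bias_factor = 20, omega0 = 50)
  log2 <- deposit_hill(log2, 0.3, 2)
  expect_equal(log2$hills$height[2], 25)
  # gamma -> infinity limit: heights stay at omega0
  log3 <- hills_log(width = 0.01, bias_factor = 1e9, omega0 = 0.8)
  for (t in 1:5) log3 <- deposit_hill(log3, 0.3, t)
  expect_equal(log3$hills$height, rep(0.8, 5), tolerance = 1e-6)
  # non-monotone deposition times are rejected
  expect_error(deposit_hill(log2, 0.3, 1.5), "non-monotone")
})

test_that("fes_from_bias applies the gamma/(gamma-1) scaling and recovers an inverse construction", {
  g <- seq(0.2, 1.0, length.out = 200)
  # gamma = 20 multiplies the negated bias by 20/19 before anchoring; a
  # bias that is an exact scaled negated copy of a curve therefore recovers
  # that curve up to its anchor
  one <- hills_log(time = 1, center = 0.5, height = 0.7, width = 0.05,
                   bias_factor = 20, omega0 = 0.8)
  fes <- fes_from_bias(one, g)
  raw <- -(20 / 19) * bias_value(one, g)
  expect_equal(fes$F, raw - min(raw), tolerance = 1e-12)
  expect_equal(attr(fes, "anchor"), "min_zero")
  expect_error(fes_from_bias(hills_log(), g), "empty hills log")
})

test_that("run_wtmtd with omega0 = 0 reduces to the unbiased sampler", {
  pot <- make_potential("mgcl")
  th <- thermo_state(seed = 21)
  mtd <- run_wtmtd(pot, th, omega0 = 0, n_steps = 5e4, record_stride = 100)
  plain <- run_langevin(pot, th, n_steps = 5e4, record_stride = 100)
  expect_equal(mtd$trajectory$s, plain$s)
  expect_equal(nrow(mtd$hills$hills), 0L)
})

test_that("run_wtmtd deposits floor(n_steps/pace) hills and visits both wells", {
  pot <- make_potential("mgcl")
  th <- thermo_state(seed = 22)
  mtd <- run_wtmtd(pot, th, n_steps = 2e6, pace = 500L, record_stride = 500L)
  expect_equal(nrow(mtd$hills$hills), floor(2e6 / 500))
  occ_cip <- mean(mtd$trajectory$s < 0.34)
  occ_ssip <- mean(mtd$trajectory$s >= 0.34 & mtd$trajectory$s < 0.6)
  expect_gt(occ_cip, 0.05)
  expect_gt(occ_ssip, 0.05)
  # heights never exceed omega0 and the first hill is full height
  expect_true(all(mtd$hills$hills$height <= 0.8 + 1e-12))
  expect_equal(mtd$hills$hills$height[1], 0.8, tolerance = 1e-9)
})

test_that("engine hill heights obey the tempering rule against the exact hill sum", {
  pot <- make_potential("mgcl")
  th <- thermo_state(seed = 23)
  mtd <- run_wtmtd(pot, th, n_steps = 5e5, pace = 500L, record_stride = 500L)
  h <- mtd$hills$hills
  kdT <- kB * 19 * 300
  v_before <- bias_value(mtd$hills, h$center, t_cutoff = h$time - 1e-9)
  expect_equal(h$height, 0.8 * exp(-v_before / kdT), tolerance = 5e-3)
})

test_that("a converged tempered run recovers the double well within 2 kJ/mol RMS", {
  pipe <- acceptance_pipeline()
  fes <- pipe$reference
  truth <- evaluate_potential(pipe$model, pipe$ref_grid)$energy
  d <- fes$F - truth
  d <- d - mean(d)
  expect_lt(sqrt(mean(d^2)), 2)
})
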