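test_that("kernel blocks match their closed forms at zero separation and at delta = theta", {
  hy <- gpr_hyper(0.4, 0.1, 0.25)
  kb <- kernel_blocks(c(0.3, 0.55), c(0.3, 0.55), hy)
  expect_equal(diag(kb$K_ff), rep(0.16, 2))
  expect_equal(diag(kb$K_fg), rep(0, 2))
  expect_equal(diag(kb$K_gg), rep(0.16 / 0.25^2, 2))
  # at separation exactly theta: K_ff = delta^2 e^{-1/2}, K_gg = 0
  kb2 <- kernel_blocks(0.3, 0.3 + 0.25, hy)
  expect_equal(kb2$K_ff[1, 1], 0.16 * exp(-0.5))
  expect_equal(kb2$K_gg[1, 1], 0)
  expect_true(isSymmetric(kb$K_gg))
})

test_that("derivative blocks match finite differences of K_ff", {
  hy <- gpr_hyper(0.7, 0.1, 0.22)
  set.seed(41)
  x <- runif(6, 0.2, 1.0); xp <- runif(6, 0.2, 1.0)
  h <- 1e-6
  kb <- kernel_blocks(x, xp, hy)
  fd_fg <- (kernel_blocks(x, xp + h, hy)$K_ff -
            kernel_blocks(x, xp - h, hy)$K_ff) / (2 * h)
  expect_equal(kb$K_fg, fd_fg, tolerance = 1e-5)
  fd_gg <- (kernel_blocks(x + h, xp, hy)$K_fg -
            kernel_blocks(x - h, xp, hy)$K_fg) / (2 * h)
  expect_equal(kb$K_gg, fd_gg, tolerance = 1e-5)
})

test_that("the dense solve equals an explicit-inversion oracle and both solver paths agree", {
  set.seed(42)
  hy <- gpr_hyper(0.65, 0.10, 0.25)
  for (n in c(20, 50, 100)) {
    s <- sort(runif(n, 0.2, 1.0)); y <- rnorm(n, 0, 10)
    tr <- training_set(s, y)
    fit <- fit_gpr_dense(tr, hy)
    K <- kernel_blocks(s, s, hy)$K_gg
    oracle <- solve(K + diag(fit$noise_sd^2 + fit$jitter_used, n), y)
    expect_lt(max(abs(fit$alpha - oracle)) / max(abs(oracle)), 1e-8)
    expect_lt(fit$resid_rel, 1e-8)
  }
  # conjugate-gradient path reproduces the Cholesky path
  s <- sort(runif(1500, 0.2, 1.0))
  pot <- make_potential("mgcl")
  tr <- training_set(s, evaluate_potential(pot, s)$gradient)
  f1 <- fit_gpr_dense(tr, hy, method = "chol")
  f2 <- fit_gpr_dense(tr, hy, method = "pcg")
  g <- seq(0.206, 0.99, length.out = 100)
  expect_lt(max(abs(predict_fes(f1, g)$F - predict_fes(f2, g)$F)), 1e-6)
  expect_lt(f2$resid_rel, 1e-8)
})

test_that("zero gradients give a zero coefficient vector and a flat curve", {
  tr <- training_set(seq(0.3, 0.7, length.out = 30), rep(0, 30))
  fit <- fit_gpr_dense(tr, gpr_hyper(0.5, 0.1, 0.25))
  expect_equal(fit$alpha, rep(0, 30))
  fes <- predict_fes(fit, seq(0.3, 0.7, length.out = 50))
  expect_equal(fes$F, rep(0, 50))
})

test_that("near-noiseless fits interpolate the training gradients", {
  set.seed(43)
  s <- c(0.4, 0.6)
  tr <- training_set(s, c(3, -2))
  fit <- fit_gpr_dense(tr, gpr_hyper(0.65, 1e-8, 0.25))
  expect_equal(predict_gradient(fit, s), c(3, -2), tolerance = 1e-6)
})

test_that("noise-free gradients of a quadratic are reconstructed to 0.05 kJ/mol", {
  a <- 40; cc <- 0.5
  s <- seq(0.3, 0.7, length.out = 100)
  tr <- training_set(s, 2 * a * (s - cc))
  fit <- fit_gpr_dense(tr, gpr_hyper(0.65, 0.05, 0.25))
  g <- seq(cc - 0.25, cc + 0.25, length.out = 200)
  pf <- predict_fes(fit, g)
  truth <- a * (g - cc)^2
  d <- pf$F - (truth - min(truth)); d <- d - mean(d)
  expect_lt(max(abs(d)), 0.05)
})

test_that("the predicted curve's numerical derivative matches the posterior gradient mean", {
  set.seed(44)
  s <- sort(runif(60, 0.3, 0.9))
  pot <- make_potential("mgcl")
  tr <- training_set(s, evaluate_potential(pot, s)$gradient)
  fit <- fit_gpr_dense(tr, gpr_hyper(0.65, 0.05, 0.22))
  h <- 1e-5
  at <- unique(round(s[10:50], 4)) # spaced points, one anchored curve for both stencils
  g_all <- sort(c(at - h, at + h))
  pf <- predict_fes(fit, g_all)$F
  fd <- (pf[match(at + h, g_all)] - pf[match(at - h, g_all)]) / (2 * h)
  expect_equal(fd, predict_gradient(fit, at), tolerance = 1e-3)
})

test_that("translating inputs and grid translates the curve exactly (stationary kernel)", {
  set.seed(45)
  s <- sort(runif(80, 0.3, 0.8)); y <- rnorm(80, 0, 20)
  hy <- gpr_hyper(0.5, 0.1, 0.25)
  f1 <- fit_gpr_dense(training_set(s, y), hy)
  f2 <- fit_gpr_dense(training_set(s + 0.13, y), hy)
  g <- seq(0.3, 0.8, length.out = 100)
  expect_equal(predict_fes(f1, g)$F, predict_fes(f2, g + 0.13)$F, tolerance = 1e-8)
})

test_that("increasing the noise shrinks the solution and smooths the curve", {
  set.seed(46)
  s <- sort(runif(150, 0.25, 0.95))
  pot <- make_potential("mgcl")
  tr <- training_set(s, evaluate_potential(pot, s)$gradient)
  g <- seq(0.25, 0.95, length.out = 200)
  norms <- tv <- numeric(0)
  for (sg in c(0.05, 0.5, 5)) {
    fit <- fit_gpr_dense(tr, gpr_hyper(0.65, sg, 0.25))
    norms <- c(norms, sqrt(sum(fit$alpha^2)))
    tv <- c(tv, sum(abs(diff(predict_fes(fit, g)$F))))
  }
  expect_true(all(diff(norms) < 0))
  expect_true(all(diff(tv) <= 1e-9))
})

test_that("inducing points at the training inputs reproduce the dense fit (lossless limit)", {
  set.seed(47)
  s <- sort(runif(120, 0.25, 0.9))
  pot <- make_potential("mgcl")
  tr <- training_set(s, evaluate_potential(pot, s)$gradient)
  hy <- gpr_hyper(0.65, 0.10, 0.25)
  fd <- fit_gpr_dense(tr, hy)
  fs <- fit_gpr_sparse(tr, hy, grid_size = length(s), inducing = s)
  g <- seq(0.25, 0.9, length.out = 150)
  expect_lt(max(abs(predict_fes(fd, g)$F - predict_fes(fs, g)$F)), 1e-6)
})

test_that("sparse fits converge to the dense fit as the grid grows", {
  set.seed(48)
  s <- sort(runif(2000, 0.206, 0.99))
  pot <- make_potential("mgcl")
  tr <- training_set(s, evaluate_potential(pot, s)$gradient)
  hy <- gpr_hyper(0.65, 0.05, 0.22)
  g <- seq(0.206, 0.99, length.out = 100)
  dense <- predict_fes(fit_gpr_dense(tr, hy), g)$F
  errs <- vapply(c(4, 8, 15, 40), function(m) {
    sp <- predict_fes(fit_gpr_sparse(tr, hy, grid_size = m), g)$F
    sqrt(mean((sp - dense)^2))
  }, 0)
  expect_true(all(diff(errs[1:3]) < 0)) # plateaus near machine level after that
  expect_lt(errs[3], 0.05)
  expect_lt(errs[4], 0.05)
})

test_that("an oversized inducing grid falls back to the dense solver with a warning", {
  tr <- training_set(seq(0.3, 0.7, length.out = 20), rnorm(20))
  expect_warning(fit <- fit_gpr_sparse(tr, gpr_hyper(0.5, 0.1, 0.25), grid_size = 50),
                 "falling back")
  expect_identical(fit$basis, "train")
})

test_that("hyperparameters must be positive", {
  expect_error(gpr_hyper(0, 0.1, 0.2), "positive")
  expect_error(gpr_hyper(0.5, -1, 0.2), "positive")
  expect_error(fit_gpr_dense(training_set(0.5, 1), gpr_hyper(0.5, 0.1, 0.2)),
               "at least 2")
})
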