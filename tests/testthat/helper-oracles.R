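# Independent oracles and small fixtures shared across the test files.
# These deliberately re-derive quantities by the dumbest possible route
# (plain loops, finite differences, explicit inversion) so they stay
# independent of the implementation paths they check.

kB <- 0.0083145
kT300 <- kB * 300

# plain-loop evaluation of a Gaussian-wells potential (+ walls)
naive_potential_eval <- function(model, s) {
  e <- numeric(length(s)); g <- numeric(length(s))
  for (i in seq_along(s)) {
    for (k in seq_len(nrow(model$wells))) {
      cc <- model$wells[k, "center"]; dd <- model$wells[k, "depth"]
      ww <- model$wells[k, "width"]
      ex <- exp(-(s[i] - cc)^2 / (2 * ww^2))
      e[i] <- e[i] - dd * ex
      g[i] <- g[i] + dd * (s[i] - cc) / ww^2 * ex
    }
    if (s[i] < model$wall$left) {
      e[i] <- e[i] + 0.5 * model$wall$stiffness * (s[i] - model$wall$left)^2
      g[i] <- g[i] + model$wall$stiffness * (s[i] - model$wall$left)
    }
    if (s[i] > model$wall$right) {
      e[i] <- e[i] + 0.5 * model$wall$stiffness * (s[i] - model$wall$right)^2
      g[i] <- g[i] + model$wall$stiffness * (s[i] - model$wall$right)
    }
  }
  list(energy = e, gradient = g)
}

# plain-loop bias sum over hills
naive_hill_sum <- function(log, s, t_cutoff = Inf, deriv = FALSE) {
  out <- numeric(length(s))
  h <- log$hills
  for (i in seq_along(s)) {
    acc <- 0
    for (j in seq_len(nrow(h))) {
      if (h$time[j] > t_cutoff) next
      d <- s[i] - h$center[j]
      e <- h$height[j] * exp(-d^2 / (2 * log$width^2))
      acc <- acc + if (deriv) -d / log$width^2 * e else e
    }
    out[i] <- acc
  }
  out
}

# central finite difference of a scalar function
fd_grad <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# a mild double-well (few kT) whose Boltzmann distribution covers the
# whole domain: usable for quantitative histogram comparisons
mild_potential <- function() {
  make_potential(wells = cbind(center = c(0.4, 0.7),
                               depth = c(8, 6), width = c(0.08, 0.08)),
                 wall = list(left = 0.25, right = 0.85, stiffness = 2000),
                 domain = c(0.2, 0.9))
}

# inverse-CDF sampler from the Boltzmann density of a model
boltzmann_direct_sample <- function(model, n, temperature = 300, seed = 1) {
  g <- seq(model$domain[1], model$domain[2], length.out = 20001)
  e <- evaluate_potential(model, g)$energy
  p <- exp(-(e - min(e)) / (kB * temperature))
  cdf <- cumsum(p); cdf <- cdf / cdf[length(cdf)]
  keep <- !duplicated(cdf)
  set.seed(seed)
  approx(cdf[keep], g[keep], xout = runif(n), rule = 2)$y
}

# the shared medium-length metadynamics pipeline used by several
# acceptance blocks (computed lazily, once per test run)
.pipeline_cache <- new.env(parent = emptyenv())
acceptance_pipeline <- function() {
  if (!is.null(.pipeline_cache$res)) return(.pipeline_cache$res)
  model <- make_potential("mgcl")
  thermo <- thermo_state(seed = 20240611L)
  mtd <- run_wtmtd(model, thermo, gamma = 20, omega0 = 0.8, sigma_g = 0.01,
                   pace = 500L, n_steps = 2.5e7, record_stride = 1000L)
  training <- unbias_gradients(mtd$trajectory, mtd$hills)
  ref_grid <- seq(0.206, 0.99, length.out = 401)
  reference <- fes_from_bias(mtd$hills, ref_grid)
  subsets <- lapply(1:5, function(k) subset_training(training, 5000, seed = 100L + k))
  names(subsets) <- paste0("batch", 1:5)
  .pipeline_cache$res <- list(model = model, thermo = thermo, mtd = mtd,
                              training = training, reference = reference,
                              ref_grid = ref_grid, subsets = subsets)
  .pipeline_cache$res
}
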