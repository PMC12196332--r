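# Langevin sampling of a 1D potential of mean force (BAOAB splitting),
# with optional harmonic restraint and optional static bias.

.default_grid_ds <- 2e-4 # nm; lookup-grid spacing for accumulated biases

.bias_grid_points <- function(model, grid_ds = .default_grid_ds) {
  n <- ceiling((model$domain[2] - model$domain[1]) / grid_ds) + 1L
  model$domain[1] + (seq_len(n) - 1L) * grid_ds
}

.argmin_potential <- function(model) {
  g <- seq(model$domain[1], model$domain[2], length.out = 2001L)
  g[which.min(evaluate_potential(model, g)$energy)]
}

#' Run Langevin dynamics on a potential model
#'
#' Integrates underdamped Langevin dynamics on
#' \eqn{U(s) = F(s) + V_{bias}(s) + (k_r/2)(s - c_r)^2} with the BAOAB
#' splitting, reflecting at the domain edges. The recorded generalized force
#' is \eqn{-d(F + V_{bias})/ds} at the sampled point (the restraint, when
#' present, is excluded from the record, matching umbrella-sampling use).
#'
#' Randomness comes from R's RNG: `set.seed(thermo$seed)` is applied before
#' integration, so identical configurations give bit-identical trajectories.
#'
#' @param model A `potential_model`.
#' @param thermo A [thermo_state()].
#' @param n_steps Number of production steps (>= 1).
#' @param bias Optional static bias: a [hills_log()] (evaluated with all its
#'   hills and tabulated on a lookup grid), or `NULL`.
#' @param restraint Optional `list(center =, k =)` harmonic restraint
#'   (kJ/mol/nm^2), as in umbrella windows.
#' @param record_stride Record every this many steps.
#' @param s0 Initial CV value; default is the potential minimum (or the
#'   restraint center when restrained).
#' @param n_equil Equilibration steps discarded before recording.
#' @param grid_ds Lookup-grid spacing for the bias (nm).
#' @return A `data.frame` of class `colvar_traj` with columns `time` (ps),
#'   `s` (nm), `gen_force` (kJ/mol/nm) and `bias` (kJ/mol).
#' @export
run_langevin <- function(model, thermo, n_steps, bias = NULL, restraint = NULL,
                         record_stride = 10L, s0 = NULL, n_equil = 0L,
                         grid_ds = .default_grid_ds) {
  stopifnot(inherits(model, "potential_model"), inherits(thermo, "thermo_state"))
  if (n_steps < 1) stop("n_steps must be >= 1")
  rk <- 0; rc <- 0
  if (!is.null(restraint)) { rk <- restraint$k; rc <- restraint$center }
  if (is.null(s0)) s0 <- if (rk > 0) rc else .argmin_potential(model)
  vb <- numeric(0); db <- numeric(0)
  if (!is.null(bias)) {
    if (!inherits(bias, "hills_log"))
      stop("'bias' must be a hills_log or NULL")
    g <- .bias_grid_points(model, grid_ds)
    vb <- bias_value(bias, g)
    db <- bias_gradient(bias, g)
  }
  set.seed(thermo$seed)
  out <- .cpp_simulate(
    model$wells[, "center"], model$wells[, "depth"], model$wells[, "width"],
    model$wall$left, model$wall$right, model$wall$stiffness,
    model$domain[1], model$domain[2],
    thermo$temperature, thermo$kB, thermo$friction, thermo$mass, thermo$dt,
    as.double(n_steps), as.double(n_equil), as.integer(record_stride), s0,
    rk, rc,
    0, 0, 0, 0L,            # metadynamics off
    grid_ds, vb, db
  )
  traj <- data.frame(time = out$time, s = out$s,
                     gen_force = out$gen_force, bias = out$bias)
  class(traj) <- c("colvar_traj", "data.frame")
  attr(traj, "dt") <- thermo$dt
  attr(traj, "record_stride") <- as.integer(record_stride)
  attr(traj, "seed") <- thermo$seed
  traj
}

#' Compare unbiased sampling against the Boltzmann prediction
#'
#' Histograms unbiased samples of the CV and compares
#' \eqn{-k_B T \ln P(s)} with the model free energy after aligning the two
#' by their mean difference over well-sampled bins. This is the basic
#' consistency check that equilibrium sampling reproduces the free energy
#' that histogram-based estimators (WHAM) target.
#'
#' @param samples Numeric vector of CV values, or a `colvar_traj`.
#' @param model A `potential_model`.
#' @param thermo A [thermo_state()] (for temperature).
#' @param n_bins Number of histogram bins (>= 10).
#' @param min_count Bins with fewer counts are excluded from the comparison.
#' @param max_empty_frac If more than this fraction of bins is empty, the
#'   result is flagged as insufficient sampling.
#' @param range Length-2 numeric: the CV interval to histogram. Defaults to
#'   the sampled range; pass the full domain to expose unvisited regions.
#' @return A list of class `boltzmann_check` with elements `statistic`
#'   (max abs deviation on well-sampled bins, kJ/mol), `rms`, `bins`
#'   (per-bin table), `empty_frac` and `insufficient`.
#' @export
boltzmann_histogram_check <- function(samples, model, thermo, n_bins = 50L,
                                      min_count = 20L, max_empty_frac = 0.2,
                                      range = NULL) {
  if (inherits(samples, "colvar_traj")) samples <- samples$s
  samples <- as.numeric(samples)
  if (n_bins < 10L) stop("n_bins must be >= 10")
  kT <- thermo$kB * thermo$temperature
  rng <- if (is.null(range)) base::range(samples) else as.numeric(range)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- tabulate(findInterval(samples, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  empty_frac <- mean(counts == 0L)
  ok <- counts >= min_count
  f_hist <- ifelse(counts > 0, -kT * log(counts / sum(counts)), NA_real_)
  f_true <- evaluate_potential(model, mid)$energy
  shift <- mean(f_hist[ok] - f_true[ok])
  dev <- f_hist - shift - f_true
  insufficient <- empty_frac > max_empty_frac
  if (insufficient)
    warning("insufficient sampling: ", sprintf("%.0f%%", 100 * empty_frac),
            " of bins in the sampled range are empty")
  structure(
    list(statistic = max(abs(dev[ok])),
         rms = sqrt(mean(dev[ok]^2)),
         bins = data.frame(s = mid, count = counts, deviation = dev,
                           well_sampled = ok),
         empty_frac = empty_frac,
         insufficient = insufficient),
    class = "boltzmann_check"
  )
}

#' @export
print.boltzmann_check <- function(x, ...) {
  cat(sprintf("<boltzmann_check> max |dev| = %.4f kJ/mol, rms = %.4f kJ/mol on %d/%d bins%s\n",
              x$statistic, x$rms, sum(x$bins$well_sampled), nrow(x$bins),
              if (x$insufficient) " [INSUFFICIENT SAMPLING]" else ""))
  invisible(x)
}
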