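# Well-tempered metadynamics: tempered hill deposition, bias evaluation,
# and the scaled-bias free energy estimate F(s) = -gamma/(gamma-1) V(s).

#' Construct a metadynamics hills log
#'
#' An ordered set of deposited Gaussians sharing one width and one bias
#' factor (the single-CV, fixed-width dialect used throughout this package).
#' Each hill contributes \eqn{\omega_k \exp(-(s-c_k)^2/(2\sigma_G^2))} to the
#' bias.
#'
#' @param time Deposition times (ps), strictly increasing.
#' @param center Hill centers (nm).
#' @param height Hill heights (kJ/mol), in `(0, omega0]`.
#' @param width Shared Gaussian width \eqn{\sigma_G} (nm).
#' @param bias_factor Well-tempering bias factor \eqn{\gamma} (> 1).
#' @param omega0 Initial hill height \eqn{\omega_0} (kJ/mol).
#' @param pace Steps between depositions (bookkeeping metadata).
#' @param temperature Simulation temperature (K), used by the tempering rule.
#' @return Object of class `hills_log`.
#' @export
hills_log <- function(time = numeric(0), center = numeric(0), height = numeric(0),
                      width = 0.01, bias_factor = 20, omega0 = 0.8,
                      pace = 500L, temperature = 300) {
  n <- length(time)
  if (length(center) != n || length(height) != n)
    stop("time, center and height must have equal length")
  if (n > 1 && any(diff(time) <= 0))
    stop("hill times must be strictly increasing (violated at row ",
         which(diff(time) <= 0)[1] + 1L, ")")
  if (width <= 0) stop("hill width must be positive")
  if (bias_factor <= 1) stop("bias_factor must be > 1")
  if (omega0 < 0) stop("omega0 must be >= 0")
  if (n > 0 && (any(height <= 0) || any(height > omega0 * (1 + 1e-12))))
    stop("hill heights must lie in (0, omega0]")
  structure(
    list(hills = data.frame(time = as.numeric(time), center = as.numeric(center),
                            height = as.numeric(height)),
         width = width, bias_factor = bias_factor, omega0 = omega0,
         pace = as.integer(pace), temperature = temperature),
    class = "hills_log"
  )
}

#' @export
print.hills_log <- function(x, ...) {
  cat(sprintf("<hills_log> %d hills, sigma_G = %g nm, gamma = %g, omega0 = %g kJ/mol\n",
              nrow(x$hills), x$width, x$bias_factor, x$omega0))
  if (nrow(x$hills) > 0)
    cat(sprintf("  time span %.3f - %.3f ps, heights %.4f - %.4f kJ/mol\n",
                min(x$hills$time), max(x$hills$time),
                min(x$hills$height), max(x$hills$height)))
  invisible(x)
}

#' Metadynamics bias potential
#'
#' \eqn{V(s, t) = \sum_{t_k \le t} \omega_k \exp(-(s-c_k)^2/(2\sigma_G^2))}.
#'
#' @param log A [hills_log()].
#' @param s CV values (nm) at which to evaluate.
#' @param t_cutoff Only hills deposited at `time <= t_cutoff` contribute.
#'   May be a scalar or one value per element of `s`.
#' @return Bias energies (kJ/mol), >= 0.
#' @export
bias_value <- function(log, s, t_cutoff = Inf) {
  .hill_sum(log, s, t_cutoff, deriv = FALSE)
}

#' Gradient of the metadynamics bias
#'
#' Exact analytic derivative of [bias_value()] with respect to the CV.
#'
#' @inheritParams bias_value
#' @return Bias gradients (kJ/mol/nm).
#' @export
bias_gradient <- function(log, s, t_cutoff = Inf) {
  .hill_sum(log, s, t_cutoff, deriv = TRUE)
}

.hill_sum <- function(log, s, t_cutoff, deriv) {
  stopifnot(inherits(log, "hills_log"))
  s <- as.numeric(s)
  if (any(!is.finite(s))) stop("non-finite CV value")
  if (nrow(log$hills) == 0) return(numeric(length(s)))
  tc <- as.numeric(t_cutoff)
  if (length(tc) != 1L && length(tc) != length(s))
    stop("t_cutoff must be scalar or match length(s)")
  .cpp_hill_sum(log$hills$center, log$hills$height, log$hills$time,
                log$width, s, tc, deriv)
}

#' Deposit one well-tempered hill
#'
#' Appends a hill at `s_current` with the tempered height
#' \eqn{\omega = \omega_0 \exp(-V(s,t) / (k_B \Delta T))}, where
#' \eqn{\Delta T = (\gamma - 1) T} and \eqn{V} is the accumulated bias from
#' all earlier hills. The first hill of an empty log has height exactly
#' \eqn{\omega_0}.
#'
#' @param log A [hills_log()].
#' @param s_current Deposition point (nm).
#' @param t Deposition time (ps), greater than the last deposition time.
#' @return The updated `hills_log`.
#' @export
deposit_hill <- function(log, s_current, t) {
  stopifnot(inherits(log, "hills_log"))
  if (nrow(log$hills) > 0 && t <= max(log$hills$time))
    stop("non-monotone deposition time: t = ", t, " <= last hill time")
  v <- bias_value(log, s_current, t)
  kdT <- .kB * (log$bias_factor - 1) * log$temperature
  h <- log$omega0 * exp(-v / kdT)
  log$hills <- rbind(log$hills,
                     data.frame(time = t, center = s_current, height = h))
  log
}

#' Free energy estimate from the converged well-tempered bias
#'
#' At long times the well-tempered bias converges to
#' \eqn{V(s) = -(1 - 1/\gamma) F(s) + C}, so the free energy is recovered as
#' \eqn{F(s) = -\gamma/(\gamma-1) \, V(s)}, anchored at minimum zero.
#'
#' @param log A non-empty [hills_log()].
#' @param grid Strictly increasing CV grid (nm).
#' @return A [fes_curve()] with anchor `"min_zero"`.
#' @export
fes_from_bias <- function(log, grid) {
  stopifnot(inherits(log, "hills_log"))
  if (nrow(log$hills) == 0) stop("empty hills log")
  scale <- log$bias_factor / (log$bias_factor - 1)
  vals <- -scale * bias_value(log, grid)
  fes_curve(grid, vals - min(vals), anchor = "min_zero")
}

#' Run a well-tempered metadynamics simulation
#'
#' Couples the Langevin sampler with tempered hill deposition every `pace`
#' steps. The accumulated bias is tabulated on a fine lookup grid (spacing
#' `grid_ds`), as metadynamics codes do, so the per-step cost is independent
#' of the number of hills. With `omega0 = 0` no hills are deposited and the
#' trajectory is identical to an unbiased [run_langevin()] under the same
#' seed.
#'
#' @param model A `potential_model`.
#' @param thermo A [thermo_state()].
#' @param gamma Bias factor (> 1).
#' @param omega0 Initial hill height (kJ/mol).
#' @param sigma_g Hill width (nm).
#' @param pace Steps between depositions.
#' @param n_steps Total integration steps.
#' @param record_stride Record every this many steps.
#' @param s0 Initial CV value (default: potential minimum).
#' @param grid_ds Bias lookup-grid spacing (nm).
#' @return List with `trajectory` (a `colvar_traj`, whose `bias` column holds
#'   the bias at each sample) and `hills` (a [hills_log()]). The number of
#'   hills is `floor(n_steps / pace)`.
#' @export
run_wtmtd <- function(model, thermo, gamma = 20, omega0 = 0.8, sigma_g = 0.01,
                      pace = 500L, n_steps, record_stride = 1000L, s0 = NULL,
                      grid_ds = .default_grid_ds) {
  stopifnot(inherits(model, "potential_model"), inherits(thermo, "thermo_state"))
  if (gamma <= 1) stop("gamma must be > 1")
  if (sigma_g <= 0) stop("sigma_g must be positive")
  if (pace < 1) stop("pace must be >= 1")
  if (is.null(s0)) s0 <- .argmin_potential(model)
  metad_pace <- if (omega0 > 0) as.integer(pace) else 0L
  set.seed(thermo$seed)
  out <- .cpp_simulate(
    model$wells[, "center"], model$wells[, "depth"], model$wells[, "width"],
    model$wall$left, model$wall$right, model$wall$stiffness,
    model$domain[1], model$domain[2],
    thermo$temperature, thermo$kB, thermo$friction, thermo$mass, thermo$dt,
    as.double(n_steps), 0, as.integer(record_stride), s0,
    0, 0,
    gamma, omega0, sigma_g, metad_pace,
    grid_ds, numeric(0), numeric(0)
  )
  traj <- data.frame(time = out$time, s = out$s,
                     gen_force = out$gen_force, bias = out$bias)
  class(traj) <- c("colvar_traj", "data.frame")
  attr(traj, "dt") <- thermo$dt
  attr(traj, "record_stride") <- as.integer(record_stride)
  attr(traj, "seed") <- thermo$seed
  hills <- hills_log(out$hill_time, out$hill_center, out$hill_height,
                     width = sigma_g, bias_factor = gamma,
                     omega0 = omega0, pace = as.integer(pace),
                     temperature = thermo$temperature)
  list(trajectory = traj, hills = hills)
}
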