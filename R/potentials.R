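# Analytic ground-truth potentials of mean force on a bounded CV domain.
#
# A potential is a sum of Gaussian wells (negative depth terms carve minima,
# a negative `depth` entry adds a repulsive bump) plus half-harmonic walls
# outside [wall$left, wall$right], on the domain [domain[1], domain[2]].

# Constants of the "mgcl" preset: a double well emulating the Mg2+ / Cl-
# ion-pairing free energy profile along the interionic distance. The two
# centers and depths solve the four conditions
#   F'(0.23) = 0, F'(0.47) = 0, F(0.47) - F(0.23) = 20 kJ/mol,
#   max(F) - F(0.47) = 30 kJ/mol on the barrier between the wells,
# so the contact-pair (CIP) minimum sits at 0.23 nm, the solvent-separated
# (SSIP) minimum at 0.47 nm (deeper CIP by 20 kJ/mol), with the barrier top
# near 0.36 nm, 30 kJ/mol above the SSIP basin and 50 kJ/mol above the CIP.
.mgcl_preset <- list(
  wells = rbind(
    c(center = 0.228030802712, depth = 111.140730077510, width = 0.08),
    c(center = 0.473053018998, depth = 90.927008941810,  width = 0.08)
  ),
  wall = list(left = 0.2, right = 1.0, stiffness = 2000),
  domain = c(0.15, 1.05)
)

#' Construct an analytic potential of mean force
#'
#' Builds a `potential_model` from a named preset or from explicit Gaussian
#' well parameters. The `"mgcl"` preset is a double well standing in for the
#' Mg2+--Cl- ion-pairing profile: local minima at 0.23 nm (contact ion pair)
#' and 0.47 nm (solvent-separated ion pair), the CIP basin 20 kJ/mol below
#' the SSIP basin, and a barrier 30 kJ/mol above the SSIP basin near 0.36 nm.
#'
#' The functional form is a sum of Gaussian terms
#' \eqn{F(s) = -\sum_k d_k \exp(-(s-c_k)^2 / (2 w_k^2))} plus half-harmonic
#' walls outside `wall$left` / `wall$right`. A negative `depth` produces a
#' repulsive bump instead of a well. The analytic gradient is exact.
#'
#' @param preset Preset name; currently `"mgcl"`. Ignored when `wells` is given.
#' @param wells Matrix (or coercible) with columns `center` (nm), `depth`
#'   (kJ/mol, positive = attractive well) and `width` (nm, > 0).
#' @param wall List with `left`, `right` (nm) and `stiffness` (kJ/mol/nm^2);
#'   half-harmonic walls applied outside `[left, right]`.
#' @param domain Length-2 numeric, the CV domain (nm); trajectories are
#'   reflected at these edges.
#' @return An object of class `potential_model`.
#' @examples
#' pot <- make_potential("mgcl")
#' evaluate_potential(pot, c(0.23, 0.47))
#' @export
make_potential <- function(preset = "mgcl", wells = NULL, wall = NULL, domain = NULL) {
  if (is.null(wells)) {
    if (!identical(preset, "mgcl"))
      stop("unknown potential preset: '", preset, "'")
    p <- .mgcl_preset
    wells <- p$wells
    if (is.null(wall)) wall <- p$wall
    if (is.null(domain)) domain <- p$domain
    name <- "mgcl"
  } else {
    wells <- as.matrix(wells)
    if (ncol(wells) != 3L) stop("'wells' must have columns center, depth, width")
    colnames(wells) <- c("center", "depth", "width")
    if (is.null(domain)) domain <- range(wells[, "center"]) + c(-0.3, 0.3)
    if (is.null(wall)) wall <- list(left = domain[1], right = domain[2], stiffness = 0)
    name <- "custom"
  }
  if (any(wells[, "width"] <= 0)) stop("well widths must be positive")
  if (!is.numeric(domain) || length(domain) != 2L || domain[1] >= domain[2])
    stop("degenerate domain: need domain[1] < domain[2]")
  if (wall$stiffness < 0) stop("wall stiffness must be >= 0")
  structure(
    list(wells = wells, wall = wall, domain = as.numeric(domain), preset = name),
    class = "potential_model"
  )
}

#' Evaluate a potential and its exact gradient
#'
#' Vectorized evaluation of \eqn{F(s)} and the analytic \eqn{dF/ds}.
#'
#' @param model A `potential_model`.
#' @param s_values Numeric vector of CV values (nm), inside the model domain.
#' @param check_domain Error on out-of-domain input (default `TRUE`).
#' @return List with numeric vectors `energy` (kJ/mol) and `gradient`
#'   (kJ/mol/nm).
#' @export
evaluate_potential <- function(model, s_values, check_domain = TRUE) {
  stopifnot(inherits(model, "potential_model"))
  s <- as.numeric(s_values)
  if (any(!is.finite(s))) stop("non-finite CV value")
  if (check_domain && (any(s < model$domain[1]) || any(s > model$domain[2])))
    stop("CV value outside the model domain [", model$domain[1], ", ", model$domain[2], "]")
  e <- numeric(length(s))
  g <- numeric(length(s))
  w <- model$wells
  for (k in seq_len(nrow(w))) {
    d <- s - w[k, "center"]
    ex <- exp(-0.5 * d^2 / w[k, "width"]^2)
    e <- e - w[k, "depth"] * ex
    g <- g + w[k, "depth"] * d / w[k, "width"]^2 * ex
  }
  wl <- model$wall
  below <- s < wl$left
  above <- s > wl$right
  e[below] <- e[below] + 0.5 * wl$stiffness * (s[below] - wl$left)^2
  g[below] <- g[below] + wl$stiffness * (s[below] - wl$left)
  e[above] <- e[above] + 0.5 * wl$stiffness * (s[above] - wl$right)^2
  g[above] <- g[above] + wl$stiffness * (s[above] - wl$right)
  list(energy = unname(e), gradient = unname(g))
}

#' @export
print.potential_model <- function(x, ...) {
  cat("<potential_model> preset:", x$preset, "\n")
  cat("  domain [nm]:", x$domain[1], "-", x$domain[2],
      " walls at", x$wall$left, "/", x$wall$right,
      "(k =", x$wall$stiffness, "kJ/mol/nm^2)\n")
  cat("  wells (center nm / depth kJ/mol / width nm):\n")
  for (k in seq_len(nrow(x$wells)))
    cat(sprintf("    %.4f / %.3f / %.3f\n",
                x$wells[k, 1], x$wells[k, 2], x$wells[k, 3]))
  invisible(x)
}

#' Thermodynamic and integrator state for the Langevin sampler
#'
#' @param temperature Temperature in K (> 0, or 0 for deterministic descent).
#' @param friction Langevin friction in 1/ps. The default 5/ps puts the CV
#'   in the diffusive (solvent-drag dominated) regime: the ballistic mean
#'   free path \eqn{\sqrt{k_B T/m}/\gamma_f \approx 0.08} nm is small
#'   against the domain, as appropriate for an interionic distance in
#'   water. Much smaller values make the 1D walker ballistic across the
#'   whole domain, which is not a meaningful solvent surrogate.
#' @param mass Effective CV mass in amu; the default is the Mg--Cl reduced
#'   mass 14.42 amu.
#' @param dt Time step in ps.
#' @param seed Integer RNG seed used by the samplers.
#' @return An object of class `thermo_state`. `kB` is fixed at
#'   0.0083145 kJ/mol/K.
#' @export
thermo_state <- function(temperature = 300, friction = 5, mass = 14.42,
                         dt = 0.002, seed = 1L) {
  if (temperature < 0) stop("temperature must be >= 0")
  if (dt <= 0) stop("dt must be positive")
  if (friction <= 0) stop("friction must be positive")
  if (mass <= 0) stop("mass must be positive")
  structure(
    list(temperature = temperature, kB = .kB, friction = friction,
         mass = mass, dt = dt, seed = as.integer(seed)),
    class = "thermo_state"
  )
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf("<thermo_state> T = %g K, friction = %g /ps, mass = %g amu, dt = %g ps, seed = %d\n",
              x$temperature, x$friction, x$mass, x$dt, x$seed))
  invisible(x)
}
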