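# Umbrella-sampling reference pipeline: window generation on the synthetic
# system and a self-consistent WHAM solver.

#' Generate umbrella window specifications
#'
#' Window centers are uniformly spaced across the span, inclusive of both
#' ends. Defaults follow the 49-window protocol on 0.206--0.99 nm with a
#' 5000 kJ/mol/nm^2 harmonic restraint.
#'
#' @param span Length-2 numeric span (nm).
#' @param n_windows Number of windows (>= 2).
#' @param spring_k Harmonic spring constant (kJ/mol/nm^2), in the
#'   \eqn{w(s) = (k/2)(s - c)^2} convention.
#' @return `data.frame` of class `umbrella_windows` with columns `center`
#'   and `spring_k`.
#' @export
make_windows <- function(span = c(0.206, 0.99), n_windows = 49L, spring_k = 5000) {
  if (n_windows < 2L) stop("need at least 2 windows")
  if (span[1] >= span[2]) stop("degenerate span")
  if (spring_k <= 0) stop("spring_k must be positive")
  out <- data.frame(center = seq(span[1], span[2], length.out = n_windows),
                    spring_k = spring_k)
  class(out) <- c("umbrella_windows", "data.frame")
  out
}

#' One sampled umbrella window
#'
#' @param center Window center (nm).
#' @param spring_k Spring constant (kJ/mol/nm^2, > 0).
#' @param samples CV samples (nm), non-empty.
#' @param time Optional sample times (ps).
#' @return Object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, spring_k, samples, time = NULL) {
  if (spring_k <= 0) stop("spring_k must be positive")
  if (length(samples) == 0) stop("a window needs at least one sample")
  structure(list(center = center, spring_k = spring_k,
                 samples = as.numeric(samples), time = time),
            class = "umbrella_window")
}

#' Sample umbrella windows on a potential model
#'
#' Runs restrained Langevin dynamics per window on
#' \eqn{U(s) = F(s) + (k/2)(s - c_i)^2}, recording the CV every `stride`
#' steps after `n_equil` equilibration steps. Each window starts at its
#' center and uses the seed `seed + window index`, so a base seed
#' reproduces the full window set exactly.
#'
#' @param model A `potential_model`.
#' @param windows An [make_windows()] table.
#' @param thermo A [thermo_state()]; its `seed` is the default base seed.
#' @param n_steps Production steps per window.
#' @param stride Recording stride (steps).
#' @param n_equil Equilibration steps per window.
#' @param seed Base seed (default `thermo$seed`).
#' @return List of [umbrella_window()] objects (class `umbrella_window_set`).
#' @export
sample_windows <- function(model, windows, thermo, n_steps = 2e6, stride = 100L,
                           n_equil = 5e4, seed = thermo$seed) {
  stopifnot(inherits(model, "potential_model"), inherits(thermo, "thermo_state"))
  out <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    th <- thermo
    th$seed <- as.integer(seed + i)
    traj <- run_langevin(model, th, n_steps,
                         restraint = list(center = windows$center[i],
                                          k = windows$spring_k[i]),
                         record_stride = stride, s0 = windows$center[i],
                         n_equil = n_equil)
    out[[i]] <- umbrella_window(windows$center[i], windows$spring_k[i],
                                traj$s, time = traj$time)
  }
  class(out) <- "umbrella_window_set"
  out
}

#' Solve the WHAM equations for a set of umbrella windows
#'
#' Iterates the coupled self-consistent equations
#' \deqn{P_j = \frac{\sum_i n_{ij}}{\sum_i N_i \exp((f_i - w_{ij})/k_B T)},
#'       \qquad e^{-f_i/k_B T} = \sum_j P_j \Delta \, e^{-w_{ij}/k_B T}}
#' with \eqn{w_{ij} = (k_i/2)(s_j - c_i)^2}, to a sup-norm change in the
#' window free energies below `tol`. The gauge is fixed by \eqn{f_1 = 0}
#' and the distribution is normalized to \eqn{\sum_j P_j \Delta = 1}.
#'
#' @param windows An `umbrella_window_set` (or list of [umbrella_window()]).
#' @param bin_edges Histogram bin edges (nm); default 0.002-nm bins over
#'   0.206--0.99 nm.
#' @param temperature Temperature (K).
#' @param tol Convergence tolerance on the window free energies (kJ/mol).
#' @param max_iter Iteration cap.
#' @param min_count Bins with fewer total counts are reported as
#'   undersampled.
#' @param drop_undersampled If `TRUE`, undersampled bins are excluded from
#'   the output curve (useful before landmark localization, where a
#'   handful of low-count bins puts kT-scale spikes into \eqn{-k_B T \ln P});
#'   default `FALSE` keeps every occupied bin.
#' @param anchor `"min_zero"` (default) anchors the output curve at 0.
#' @return Object of class `wham_result`: `fes` (a [fes_curve()] on occupied
#'   bin centers), `window_free_energies`, `n_iterations`, `final_change`,
#'   `converged`, `undersampled_bins`, `bin_centers`, `counts`.
#' @export
wham_solve <- function(windows, bin_edges = seq(0.206, 0.99, by = 0.002),
                       temperature = 300, tol = 1e-8, max_iter = 1e6,
                       min_count = 10L, drop_undersampled = FALSE,
                       anchor = "min_zero") {
  if (inherits(windows, "umbrella_window")) windows <- list(windows)
  nw <- length(windows)
  if (nw == 0) stop("no windows")
  kT <- .kB * temperature
  nb <- length(bin_edges) - 1L
  mid <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  db <- diff(bin_edges)
  counts <- matrix(0, nw, nb)
  for (i in seq_len(nw)) {
    idx <- findInterval(windows[[i]]$samples, bin_edges, rightmost.closed = TRUE)
    counts[i, ] <- tabulate(idx[idx >= 1L & idx <= nb], nbins = nb)
  }
  N <- rowSums(counts)
  if (any(N == 0)) stop("window ", which(N == 0)[1], " has no samples inside the bin range")

  # overlap check between center-adjacent windows
  ord <- order(vapply(windows, function(w) w$center, 0))
  occ <- counts > 0
  for (k in seq_len(nw - 1L)) {
    i1 <- ord[k]; i2 <- ord[k + 1L]
    if (!any(occ[i1, ] & occ[i2, ]))
      stop(sprintf(paste0("non-overlapping windows: no shared occupied bin between ",
                          "window centers %.4f and %.4f nm (disconnected span)"),
                   windows[[i1]]$center, windows[[i2]]$center))
  }

  w_mat <- matrix(0, nw, nb) # restraint energy at bin centers
  for (i in seq_len(nw))
    w_mat[i, ] <- 0.5 * windows[[i]]$spring_k * (mid - windows[[i]]$center)^2
  E <- exp(-w_mat / kT)      # nw x nb
  csum <- colSums(counts)
  f <- numeric(nw)
  change <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    z <- exp(f / kT)
    denom <- as.numeric(crossprod(E, N * z))     # length nb
    P <- ifelse(denom > 0, csum / denom, 0)
    P <- P / sum(P * db)
    f_new <- -kT * log(as.numeric(E %*% (P * db)))
    change <- max(abs(f_new - f))
    f <- f_new
    if (change <= tol) break
  }
  f <- f - f[1] # report in the f_1 = 0 gauge
  keep <- csum > 0 & is.finite(P) & P > 0
  if (drop_undersampled) keep <- keep & csum >= min_count
  Fv <- -kT * log(P[keep])
  if (identical(anchor, "min_zero")) Fv <- Fv - min(Fv)
  structure(
    list(fes = fes_curve(mid[keep], Fv, anchor = anchor),
         window_free_energies = f,
         n_iterations = it,
         final_change = change,
         converged = change <= tol,
         undersampled_bins = which(csum < min_count),
         bin_centers = mid,
         counts = counts,
         prob = P,
         temperature = temperature),
    class = "wham_result"
  )
}

#' @export
print.wham_result <- function(x, ...) {
  cat(sprintf("<wham_result> %d windows, %d bins (%d undersampled), %s in %d iterations (last change %.2e kJ/mol)\n",
              nrow(x$counts), length(x$bin_centers), length(x$undersampled_bins),
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations, x$final_change))
  invisible(x)
}
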