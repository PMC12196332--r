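# Quantitative comparison of free energy curves: 100-point error norms,
# landmark (CIP/SSIP/barrier) localization, hyperparameter sweeps and
# sweep summaries.

#' Error norm between two free energy curves
#'
#' Both curves are linearly interpolated at `n_points` uniform points over
#' the intersection of their spans; after the chosen alignment, the
#' Euclidean norm of the difference vector is returned together with the
#' norm divided by the number of evaluation points ("error per data
#' point").
#'
#' @param fes_a,fes_b [fes_curve()] objects with overlapping spans.
#' @param n_points Number of evaluation points (default 100).
#' @param alignment `"mean"` (default) subtracts the mean difference before
#'   taking the norm (gradient-trained reconstructions carry an arbitrary
#'   constant); `"none"` compares raw values; `"anchor_min"` shifts each
#'   curve to minimum zero first.
#' @return List with `norm` (kJ/mol), `per_point`, `n_points`, `span`.
#' @export
error_norm <- function(fes_a, fes_b, n_points = 100L,
                       alignment = c("mean", "none", "anchor_min")) {
  alignment <- match.arg(alignment)
  lo <- max(min(fes_a$s), min(fes_b$s))
  hi <- min(max(fes_a$s), max(fes_b$s))
  if (lo >= hi) stop("disjoint spans: the curves share no CV interval")
  x <- seq(lo, hi, length.out = n_points)
  va <- .fes_interp(fes_a, x)
  vb <- .fes_interp(fes_b, x)
  if (alignment == "anchor_min") {
    va <- va - min(va)
    vb <- vb - min(vb)
  }
  d <- va - vb
  if (alignment == "mean") d <- d - mean(d)
  nrm <- sqrt(sum(d^2))
  list(norm = nrm, per_point = nrm / n_points, n_points = n_points,
       span = c(lo, hi))
}

.refine_extremum <- function(s, v, i, halfwidth = 2L) {
  lo <- max(1L, i - halfwidth)
  hi <- min(length(s), i + halfwidth)
  if (hi - lo < 2L) return(s[i])
  x <- s[lo:hi] - s[i]
  fit <- coef(lm(v[lo:hi] ~ x + I(x^2)))
  if (!is.finite(fit[3]) || fit[3] == 0) return(s[i])
  vertex <- -fit[2] / (2 * fit[3])
  # keep the refinement inside the fitting stencil
  if (abs(vertex) > (s[hi] - s[lo]) / 2) return(s[i])
  s[i] + vertex
}

#' Locate the landmarks of a double-well free energy curve
#'
#' Finds interior local minima and maxima by discrete sign changes of the
#' finite differences, refined by a local quadratic fit. For an ion-pairing
#' profile the contact-pair (CIP) minimum is the leftmost minimum, the
#' solvent-separated (SSIP) minimum the next one, and the barrier the
#' highest maximum between them. With fewer than two minima a partial
#' report (NA fields) is returned.
#'
#' @param fes A [fes_curve()] with at least 5 grid points.
#' @param refine_halfwidth Half-width (grid points) of the quadratic
#'   refinement stencil.
#' @param min_prominence Extrema whose value differs from an adjacent
#'   extremum by less than this (kJ/mol) are treated as noise wiggles and
#'   pruned (persistence simplification). The default 2 kJ/mol sits well
#'   below the basin/barrier scale of ion-pairing profiles but above the
#'   statistical roughness of converged reconstructions.
#' @return Object of class `landmark_report` with fields `cip_s`, `ssip_s`,
#'   `barrier_s` (nm), `barrier_from_cip`, `barrier_from_ssip`,
#'   `ssip_minus_cip` (kJ/mol), `minima_s`, `maxima_s`, `complete`.
#' @export
locate_landmarks <- function(fes, refine_halfwidth = 2L, min_prominence = 2) {
  stopifnot(inherits(fes, "fes_curve"))
  if (nrow(fes) < 5L) stop("need at least 5 grid points")
  s <- fes$s; v <- fes$F
  sgn <- sign(diff(v))
  sgn[sgn == 0] <- 1e-12 # flat segments do not create spurious extrema
  flips <- diff(sgn)
  i_min <- which(flips > 1) + 1L
  i_max <- which(flips < -1) + 1L
  # persistence pruning: repeatedly merge the adjacent extremum pair with
  # the smallest value separation until all pairs clear min_prominence
  ext <- data.frame(i = c(i_min, i_max),
                    kind = rep(c("min", "max"), c(length(i_min), length(i_max))))
  ext <- ext[order(ext$i), , drop = FALSE]
  while (nrow(ext) >= 2L) {
    gaps <- abs(diff(v[ext$i]))
    k <- which.min(gaps)
    if (gaps[k] >= min_prominence) break
    ext <- ext[-c(k, k + 1L), , drop = FALSE]
  }
  i_min <- ext$i[ext$kind == "min"]
  i_max <- ext$i[ext$kind == "max"]
  minima <- vapply(i_min, function(i) .refine_extremum(s, v, i, refine_halfwidth), 0)
  maxima <- vapply(i_max, function(i) .refine_extremum(s, v, i, refine_halfwidth), 0)
  out <- list(cip_s = NA_real_, ssip_s = NA_real_, barrier_s = NA_real_,
              barrier_from_cip = NA_real_, barrier_from_ssip = NA_real_,
              ssip_minus_cip = NA_real_,
              minima_s = minima, maxima_s = maxima, complete = FALSE)
  interp <- function(x) .fes_interp(fes, x)
  if (length(minima) >= 1L) out$cip_s <- minima[1]
  if (length(minima) >= 2L) {
    out$ssip_s <- minima[2]
    between <- maxima[maxima > out$cip_s & maxima < out$ssip_s]
    if (length(between) >= 1L) {
      vals <- interp(between)
      out$barrier_s <- between[which.max(vals)]
      fb <- max(vals)
      out$barrier_from_cip <- fb - interp(out$cip_s)
      out$barrier_from_ssip <- fb - interp(out$ssip_s)
      out$complete <- TRUE
    }
    out$ssip_minus_cip <- interp(out$ssip_s) - interp(out$cip_s)
  }
  class(out) <- "landmark_report"
  out
}

#' @export
print.landmark_report <- function(x, ...) {
  cat("<landmark_report>\n")
  cat(sprintf("  CIP minimum:     %s nm\n", format(x$cip_s, digits = 4)))
  cat(sprintf("  SSIP minimum:    %s nm (SSIP - CIP = %s kJ/mol)\n",
              format(x$ssip_s, digits = 4), format(x$ssip_minus_cip, digits = 4)))
  cat(sprintf("  barrier:         %s nm (%s above CIP, %s above SSIP, kJ/mol)\n",
              format(x$barrier_s, digits = 4),
              format(x$barrier_from_cip, digits = 4),
              format(x$barrier_from_ssip, digits = 4)))
  if (!x$complete) cat("  [partial report: fewer than two minima plus barrier]\n")
  invisible(x)
}

#' Hyperparameter sweep of GPR reconstructions against a reference curve
#'
#' Fits a GP for every combination of hyperparameters, training set, mode
#' and (for sparse mode) grid size, predicts the free energy on a uniform
#' grid and records the error norm against the reference. Individual fit
#' failures are recorded as failed cells rather than aborting the sweep.
#'
#' @param train_sets A [training_set()] or named list of them.
#' @param reference A [fes_curve()] used as comparison surface.
#' @param deltas,sigmas,thetas Hyperparameter grids.
#' @param mode `"dense"`, `"sparse"`, or both.
#' @param grid_sizes Inducing-grid sizes for sparse mode.
#' @param n_points Evaluation points for the error norm.
#' @param alignment Alignment passed to [error_norm()].
#' @param noise_mode Passed to the fitting routines.
#' @param span Prediction span (nm); predictions use `n_points` uniform
#'   points on it.
#' @param method Dense solver selection, see [fit_gpr_dense()].
#' @return `data.frame` of class `sweep_records` with one row per cell:
#'   columns `subset`, `mode`, `grid_size`, `delta`, `sigma`, `theta`,
#'   `error_norm`, `error_per_point`, `failed`.
#' @export
run_sweep <- function(train_sets, reference,
                      deltas = c(0.40, 0.65, 0.90),
                      sigmas = c(0.05, 0.10, 0.15),
                      thetas = seq(0.20, 0.35, by = 0.01),
                      mode = "dense", grid_sizes = NULL,
                      n_points = 100L, alignment = "mean",
                      noise_mode = "direct", span = c(0.206, 0.99),
                      method = "auto") {
  if (inherits(train_sets, "training_set")) train_sets <- list(set1 = train_sets)
  if (is.null(names(train_sets)))
    names(train_sets) <- paste0("set", seq_along(train_sets))
  stopifnot(inherits(reference, "fes_curve"))
  grid_s <- seq(span[1], span[2], length.out = n_points)
  cells <- expand.grid(theta = thetas, sigma = sigmas, delta = deltas,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  variants <- list()
  for (md in mode) {
    if (md == "dense") {
      variants[[length(variants) + 1L]] <- list(mode = "dense", grid_size = NA_integer_)
    } else if (md == "sparse") {
      if (is.null(grid_sizes)) stop("sparse mode requires grid_sizes")
      for (g in grid_sizes)
        variants[[length(variants) + 1L]] <- list(mode = "sparse", grid_size = as.integer(g))
    } else stop("unknown mode: ", md)
  }
  rows <- vector("list", length(train_sets) * length(variants) * nrow(cells))
  r <- 0L
  for (set_name in names(train_sets)) {
    train <- train_sets[[set_name]]
    for (vt in variants) {
      for (i in seq_len(nrow(cells))) {
        hy <- gpr_hyper(cells$delta[i], cells$sigma[i], cells$theta[i])
        rec <- tryCatch({
          fit <- if (vt$mode == "dense")
            fit_gpr_dense(train, hy, noise_mode = noise_mode, method = method)
          else
            fit_gpr_sparse(train, hy, grid_size = vt$grid_size,
                           span = span, noise_mode = noise_mode)
          fes <- predict_fes(fit, grid_s)
          en <- error_norm(fes, reference, n_points = n_points, alignment = alignment)
          c(en$norm, en$per_point, 0)
        }, error = function(e) c(NA_real_, NA_real_, 1))
        r <- r + 1L
        rows[[r]] <- data.frame(subset = set_name, mode = vt$mode,
                                grid_size = vt$grid_size,
                                delta = cells$delta[i], sigma = cells$sigma[i],
                                theta = cells$theta[i],
                                error_norm = rec[1], error_per_point = rec[2],
                                failed = rec[3] == 1)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_records", "data.frame")
  attr(out, "span") <- span
  attr(out, "alignment") <- alignment
  attr(out, "noise_mode") <- noise_mode
  out
}

#' Best (error-minimizing) sweep rows per group
#'
#' @param records A `sweep_records` table.
#' @param by Grouping columns (default subset/mode/grid_size).
#' @param tie_tol Rows within this absolute tolerance of the group minimum
#'   count as tied and are all returned, ordered by (delta, sigma, theta).
#' @return `data.frame` of argmin rows.
#' @export
sweep_argmin <- function(records, by = c("subset", "mode", "grid_size"),
                         tie_tol = 1e-12) {
  ok <- records[!records$failed & is.finite(records$error_norm), , drop = FALSE]
  if (nrow(ok) == 0) stop("no successful sweep cells")
  # NA grid_size (dense mode) must stay a real group level
  key <- interaction(lapply(ok[by], function(x) addNA(factor(x), ifany = TRUE)),
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(ok, key), function(g) {
    best <- min(g$error_norm)
    tied <- g[g$error_norm <= best + tie_tol, , drop = FALSE]
    tied[order(tied$delta, tied$sigma, tied$theta), , drop = FALSE]
  }))
  rownames(out) <- NULL
  out
}

#' Summarize a hyperparameter sweep
#'
#' Collects the best rows per group, optional landmark tables, and
#' heatmap-ready error-norm matrices (sigma rows by theta columns at each
#' delta).
#'
#' @param records A `sweep_records` table.
#' @param landmarks Optional named list of `landmark_report` objects to
#'   include in the report.
#' @return Object of class `sweep_summary` with elements `best`,
#'   `heatmaps`, `landmarks` and `lines` (a plain-text report).
#' @export
summarize_sweep <- function(records, landmarks = NULL) {
  best <- sweep_argmin(records)
  heatmaps <- list()
  ok <- records[!records$failed, , drop = FALSE]
  for (key in unique(paste(ok$subset, ok$mode, ok$grid_size, sep = "|"))) {
    sub <- ok[paste(ok$subset, ok$mode, ok$grid_size, sep = "|") == key, , drop = FALSE]
    for (d in unique(sub$delta)) {
      sd <- sub[sub$delta == d, , drop = FALSE]
      sig <- sort(unique(sd$sigma)); th <- sort(unique(sd$theta))
      m <- matrix(NA_real_, length(sig), length(th),
                  dimnames = list(sigma = as.character(sig), theta = as.character(th)))
      for (i in seq_len(nrow(sd)))
        m[match(sd$sigma[i], sig), match(sd$theta[i], th)] <- sd$error_norm[i]
      heatmaps[[paste0(key, "|delta=", format(d))]] <- m
    }
  }
  lines <- c("hyperparameter sweep summary",
             sprintf("  %d records, %d failed", nrow(records), sum(records$failed)),
             "best rows per (subset, mode, grid_size):")
  for (i in seq_len(nrow(best)))
    lines <- c(lines, sprintf("  %s %s gs=%s  delta=%.2f sigma=%.2f theta=%.2f  norm=%.3f (%.4f / point)",
                              best$subset[i], best$mode[i], format(best$grid_size[i]),
                              best$delta[i], best$sigma[i], best$theta[i],
                              best$error_norm[i], best$error_per_point[i]))
  if (!is.null(landmarks)) {
    lines <- c(lines, "landmarks:")
    for (nm in names(landmarks)) {
      lk <- landmarks[[nm]]
      lines <- c(lines, sprintf("  %s: CIP %.4f nm, SSIP %.4f nm, barrier %.4f nm, SSIP-CIP %.2f kJ/mol, barrier-from-SSIP %.2f kJ/mol",
                                nm, lk$cip_s, lk$ssip_s, lk$barrier_s,
                                lk$ssip_minus_cip, lk$barrier_from_ssip))
    }
  }
  structure(list(best = best, heatmaps = heatmaps, landmarks = landmarks,
                 lines = lines),
            class = "sweep_summary")
}

#' @export
print.sweep_summary <- function(x, ...) {
  cat(paste(x$lines, collapse = "\n"), "\n")
  invisible(x)
}
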