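# Turning biased trajectory frames into unbiased free-energy-derivative
# training data: analytic CV Jacobians, biased gradient estimates, and
# causal subtraction of the metadynamics bias gradient.

#' Analytic Jacobian of a distance collective variable
#'
#' For the distance \eqn{d = |r_a - r_b|} between two atoms, returns the
#' exact Jacobians \eqn{\partial d/\partial r_a = (r_a - r_b)/d} and its
#' negative for atom b. Both are unit vectors.
#'
#' @param r_a,r_b Length-3 position vectors (nm), not coincident.
#' @return List with `d` (nm), `j_a` and `j_b` (unit 3-vectors).
#' @export
distance_cv_jacobian <- function(r_a, r_b) {
  r_a <- as.numeric(r_a); r_b <- as.numeric(r_b)
  stopifnot(length(r_a) == 3L, length(r_b) == 3L)
  dvec <- r_a - r_b
  d <- sqrt(sum(dvec^2))
  if (d == 0) stop("coincident atoms: the distance Jacobian is undefined")
  j <- dvec / d
  list(d = d, j_a = j, j_b = -j)
}

#' Per-frame biased free-energy-derivative estimate
#'
#' Estimates \eqn{g_b = d(F + V_{bias})/ds} for each frame. Two input modes:
#' \describe{
#'   \item{synthetic}{a `colvar_traj` (or data frame with a `gen_force`
#'     column): \eqn{g_b = -} `gen_force`, since the recorded generalized
#'     force is \eqn{-d(F+V_{bias})/ds}.}
#'   \item{atomistic}{a list with n-by-3 matrices `r_a`, `r_b`, `f_a`, `f_b`
#'     of positions and forces for the two atoms defining the distance CV:
#'     the atomic forces are projected through the analytic Jacobian,
#'     \eqn{g_b = -(f_a \cdot j_a + f_b \cdot j_b)}.}
#' }
#'
#' @param frames Trajectory frames in either mode.
#' @return Numeric vector of biased derivative estimates (kJ/mol/nm).
#' @export
biased_gradient_estimate <- function(frames) {
  if (is.data.frame(frames)) {
    if (!"gen_force" %in% names(frames))
      stop("missing force record: no 'gen_force' column")
    return(-frames$gen_force)
  }
  if (is.list(frames) && all(c("r_a", "r_b", "f_a", "f_b") %in% names(frames))) {
    ra <- as.matrix(frames$r_a); rb <- as.matrix(frames$r_b)
    fa <- as.matrix(frames$f_a); fb <- as.matrix(frames$f_b)
    dvec <- ra - rb
    d <- sqrt(rowSums(dvec^2))
    if (any(d == 0)) stop("coincident atoms: the distance Jacobian is undefined")
    ja <- dvec / d
    -(rowSums(fa * ja) + rowSums(fb * -ja))
  } else {
    stop("missing force record: frames must carry 'gen_force' or atomistic r/f matrices")
  }
}

#' Construct a training set of unbiased free energy derivatives
#'
#' @param s CV values (nm).
#' @param y Unbiased derivative estimates dF/ds (kJ/mol/nm), finite.
#' @param frame_index Integer frame indices (unique).
#' @param time Frame times (ps).
#' @param source Optional provenance list.
#' @return Object of class `training_set` (a `data.frame` with columns
#'   `s`, `y`, `frame`, `time`).
#' @export
training_set <- function(s, y, frame_index = seq_along(s), time = rep(0, length(s)),
                         source = list()) {
  if (length(s) == 0) stop("a training set must be non-empty")
  if (anyDuplicated(frame_index)) stop("duplicated frame_index in training set")
  if (any(!is.finite(y))) stop("non-finite derivative in training set")
  out <- data.frame(s = as.numeric(s), y = as.numeric(y),
                    frame = as.integer(frame_index), time = as.numeric(time))
  class(out) <- c("training_set", "data.frame")
  attr(out, "source") <- source
  out
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> %d gradient samples, s in [%.4f, %.4f] nm\n",
              nrow(x), min(x$s), max(x$s)))
  src <- attr(x, "source")
  if (length(src)) cat("  source:", paste(names(src), unlist(lapply(src, format)),
                                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Unbias trajectory gradients against a hills log
#'
#' For each frame computes the unbiased free energy derivative
#' \eqn{y = g_b - dV_{bias}/ds} where the bias gradient is evaluated
#' causally: only hills deposited at or before the frame time contribute.
#' Frames predating the first hill keep a zero bias correction. Non-finite
#' results are dropped with a message.
#'
#' @param frames A `colvar_traj` (columns `time`, `s`, `gen_force`).
#' @param log A [hills_log()] (may be empty, in which case `y = g_b`).
#' @return A [training_set()].
#' @export
unbias_gradients <- function(frames, log) {
  stopifnot(is.data.frame(frames), inherits(log, "hills_log"))
  gb <- biased_gradient_estimate(frames)
  corr <- if (nrow(log$hills) > 0)
    bias_gradient(log, frames$s, t_cutoff = frames$time)
  else numeric(nrow(frames))
  y <- gb - corr
  keep <- is.finite(y)
  if (!all(keep))
    message("dropped ", sum(!keep), " frame(s) with non-finite unbiased derivative")
  training_set(frames$s[keep], y[keep],
               frame_index = seq_len(nrow(frames))[keep],
               time = frames$time[keep],
               source = list(n_frames = nrow(frames), n_hills = nrow(log$hills)))
}

#' Random subset of a training set
#'
#' Uniform sampling without replacement, seed-deterministic; used to build
#' the reduced training datasets for hyperparameter sweeps.
#'
#' @param full A [training_set()].
#' @param n Subset size (<= `nrow(full)`).
#' @param seed Integer seed.
#' @return A [training_set()] with provenance `(n, seed)`.
#' @export
subset_training <- function(full, n, seed) {
  stopifnot(inherits(full, "training_set"))
  if (n > nrow(full)) stop("requested subset of ", n, " from only ", nrow(full), " samples")
  set.seed(seed)
  idx <- sort(sample.int(nrow(full), n))
  src <- attr(full, "source")
  src$subset_n <- n
  src$subset_seed <- seed
  training_set(full$s[idx], full$y[idx], frame_index = full$frame[idx],
               time = full$time[idx], source = src)
}
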