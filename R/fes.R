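# Tabulated free energy curves: the common currency of all pipeline stages.

#' Construct a tabulated free energy curve
#'
#' @param grid_s Strictly increasing CV grid (nm).
#' @param values Free energies (kJ/mol), finite, same length as `grid_s`.
#' @param anchor Anchoring convention tag, e.g. `"min_zero"` or `"none"`.
#' @return Object of class `fes_curve` (also a `data.frame` with columns
#'   `s` and `F`).
#' @export
fes_curve <- function(grid_s, values, anchor = "none") {
  grid_s <- as.numeric(grid_s)
  values <- as.numeric(values)
  if (length(grid_s) != length(values)) stop("grid and values differ in length")
  if (length(grid_s) < 2L) stop("a curve needs at least two grid points")
  if (any(diff(grid_s) <= 0)) stop("grid must be strictly increasing")
  if (any(!is.finite(values))) stop("non-finite free energy values")
  out <- data.frame(s = grid_s, F = values)
  class(out) <- c("fes_curve", "data.frame")
  attr(out, "anchor") <- anchor
  out
}

#' @export
print.fes_curve <- function(x, ...) {
  cat(sprintf("<fes_curve> %d points on [%.4f, %.4f] nm, range %.3f - %.3f kJ/mol (anchor: %s)\n",
              nrow(x), min(x$s), max(x$s), min(x$F), max(x$F),
              attr(x, "anchor") %||% "none"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# linear interpolation of a curve at arbitrary points within its span
.fes_interp <- function(fes, x) {
  approx(fes$s, fes$F, xout = x, rule = 1)$y
}
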