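#' Natural cubic spline specification
#'
#' Defines the natural-cubic-spline basis used for the subject-specific
#' square-root CD4 trajectory. The basis is built from a cubic B-spline basis
#' with the natural (zero second derivative) constraints at the boundary knots
#' imposed through a null-space projection, together with a zero-value
#' constraint at the lower boundary so that the constant function is excluded
#' (the model carries its own intercept). Outside the boundary knots every
#' basis function continues along its tangent line, so trajectories can be
#' evaluated at event times beyond the last measurement time.
#'
#' @param boundary_knots length-2 numeric, lower and upper boundary (months).
#' @param interior_knots ordered numeric vector of interior knots, strictly
#'   inside the boundary; length K >= 1. The trajectory model uses K = 1 with
#'   the knot at the median of the pooled observed measurement times.
#' @return an object of class `ncs_spec` with `K + 1` basis columns.
#' @examples
#' sp <- ncs_spec(c(0, 24), 9)
#' ncs_basis(c(0, 6, 12, 30), sp)
#' @export
ncs_spec <- function(boundary_knots, interior_knots) {
  boundary_knots <- as.numeric(boundary_knots)
  interior_knots <- as.numeric(interior_knots)
  if (length(boundary_knots) != 2L || any(!is.finite(boundary_knots)) ||
      boundary_knots[1L] >= boundary_knots[2L])
    stop("boundary_knots must be two finite increasing values")
  if (length(interior_knots) < 1L || any(!is.finite(interior_knots)))
    stop("at least one finite interior knot is required")
  if (is.unsorted(interior_knots, strictly = TRUE))
    stop("interior knots must be strictly increasing (no duplicates)")
  if (any(interior_knots <= boundary_knots[1L]) ||
      any(interior_knots >= boundary_knots[2L]))
    stop("interior knots must lie strictly inside the boundary knots")

  lo <- boundary_knots[1L]; hi <- boundary_knots[2L]
  knots_aug <- c(rep(lo, 4L), interior_knots, rep(hi, 4L))
  nb <- length(interior_knots) + 4L
  # constraints: f''(lo) = 0, f''(hi) = 0, f(lo) = 0
  C <- splines::splineDesign(knots_aug, x = c(lo, hi, lo), ord = 4L,
                             derivs = c(2L, 2L, 0L))
  Q <- qr.Q(qr(t(C)), complete = TRUE)
  N <- Q[, 4:nb, drop = FALSE] # null space of the constraints: K + 1 columns

  spec <- structure(list(
    boundary_knots = c(lo, hi),
    interior_knots = interior_knots,
    intercept_excluded = TRUE,
    knots_aug = knots_aug,
    null_basis = N
  ), class = "ncs_spec")
  # tangent-line data at the boundaries for linear extrapolation
  spec$edge <- list(
    v_lo = .ncs_inside(lo, spec), d_lo = .ncs_inside(lo, spec, derivs = 1L),
    v_hi = .ncs_inside(hi, spec), d_hi = .ncs_inside(hi, spec, derivs = 1L)
  )
  spec
}

#' @export
print.ncs_spec <- function(x, ...) {
  cat("Natural cubic spline basis (", ncol(x$null_basis), " columns)\n",
      "  boundary knots: ", x$boundary_knots[1L], ", ", x$boundary_knots[2L],
      "\n  interior knots: ", paste(x$interior_knots, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

.ncs_inside <- function(times, spec, derivs = 0L) {
  splines::splineDesign(spec$knots_aug, x = times, ord = 4L,
                        derivs = rep(derivs, length(times))) %*% spec$null_basis
}

#' Natural cubic spline basis, derivative and integral
#'
#' `ncs_basis()` evaluates the natural cubic spline design matrix (no
#' intercept column); `ncs_basis_deriv()` its exact analytic first
#' derivative; `ncs_basis_integral()` the column-wise integral from 0,
#' exact for the piecewise-cubic (linear-tailed) form. Evaluation beyond the
#' boundary knots follows each basis function's tangent line, so the basis is
#' C2 inside and exactly linear outside.
#'
#' @param times numeric vector of evaluation times (months); must be
#'   nonnegative for the integral.
#' @param spec an [ncs_spec()].
#' @return numeric matrix, `length(times)` rows and `K + 1` columns.
#' @export
ncs_basis <- function(times, spec) {
  stopifnot(inherits(spec, "ncs_spec"))
  times <- as.numeric(times)
  if (any(!is.finite(times))) stop("times must be finite")
  lo <- spec$boundary_knots[1L]; hi <- spec$boundary_knots[2L]
  out <- matrix(0, length(times), ncol(spec$null_basis))
  ins <- times >= lo & times <= hi
  if (any(ins)) out[ins, ] <- .ncs_inside(times[ins], spec)
  low <- times < lo
  if (any(low))
    out[low, ] <- rep(1, sum(low)) %*% spec$edge$v_lo +
      (times[low] - lo) %*% spec$edge$d_lo
  high <- times > hi
  if (any(high))
    out[high, ] <- rep(1, sum(high)) %*% spec$edge$v_hi +
      (times[high] - hi) %*% spec$edge$d_hi
  out
}

#' @rdname ncs_basis
#' @export
ncs_basis_deriv <- function(times, spec) {
  stopifnot(inherits(spec, "ncs_spec"))
  times <- as.numeric(times)
  if (any(!is.finite(times))) stop("times must be finite")
  lo <- spec$boundary_knots[1L]; hi <- spec$boundary_knots[2L]
  out <- matrix(0, length(times), ncol(spec$null_basis))
  ins <- times >= lo & times <= hi
  if (any(ins)) out[ins, ] <- .ncs_inside(times[ins], spec, derivs = 1L)
  low <- times < lo
  if (any(low)) out[low, ] <- rep(1, sum(low)) %*% spec$edge$d_lo
  high <- times > hi
  if (any(high)) out[high, ] <- rep(1, sum(high)) %*% spec$edge$d_hi
  out
}

#' @rdname ncs_basis
#' @export
ncs_basis_integral <- function(times, spec) {
  stopifnot(inherits(spec, "ncs_spec"))
  times <- as.numeric(times)
  if (any(!is.finite(times))) stop("times must be finite")
  if (any(times < 0)) stop("integral requires nonnegative times")
  # piecewise-polynomial pieces: integrate with a 5-point rule per piece,
  # exact for cubics; accumulate exact values at the breakpoints once.
  bp <- sort(unique(c(0, spec$boundary_knots, spec$interior_knots)))
  bp <- bp[bp >= 0]
  if (bp[1L] > 0) bp <- c(0, bp)
  gl <- gauss_legendre(5L)
  piece_int <- function(a, b) { # integral of each basis column over [a, b]
    if (b <= a) return(numeric(ncol(spec$null_basis)))
    s <- (b - a) / 2 * gl$nodes + (a + b) / 2
    drop(((b - a) / 2 * gl$weights) %*% ncs_basis(s, spec))
  }
  cum <- matrix(0, length(bp), ncol(spec$null_basis))
  for (j in seq_along(bp)[-1L])
    cum[j, ] <- cum[j - 1L, ] + piece_int(bp[j - 1L], bp[j])
  idx <- findInterval(times, bp) # piece containing each time
  out <- matrix(0, length(times), ncol(spec$null_basis))
  for (i in seq_along(times)) {
    j <- idx[i]
    out[i, ] <- cum[j, ] + piece_int(bp[j], times[i])
  }
  out
}

#' B-spline specification for the log baseline hazard
#'
#' The log baseline hazard is an explicit intercept plus a B-spline expansion
#' over the follow-up period. Default degree is cubic with interior knots at
#' equally spaced percentiles of the observed event times.
#'
#' @param boundary_knots length-2 numeric (months), the follow-up range.
#' @param interior_knots numeric vector of `Q >= 0` interior knots, strictly
#'   inside the boundary.
#' @param degree spline degree `g >= 1` (3 = cubic, the default).
#' @return an object of class `bspline_spec` whose basis has `Q + g + 1`
#'   columns.
#' @export
bspline_spec <- function(boundary_knots, interior_knots = numeric(),
                         degree = 3L) {
  boundary_knots <- as.numeric(boundary_knots)
  interior_knots <- as.numeric(interior_knots)
  degree <- as.integer(degree)
  if (length(boundary_knots) != 2L || boundary_knots[1L] >= boundary_knots[2L])
    stop("boundary_knots must be two increasing values")
  if (degree < 1L) stop("degree must be >= 1")
  if (length(interior_knots)) {
    if (is.unsorted(interior_knots, strictly = TRUE))
      stop("interior knots must be strictly increasing (no duplicates)")
    if (any(interior_knots <= boundary_knots[1L]) ||
        any(interior_knots >= boundary_knots[2L]))
      stop("interior knots must lie strictly inside the boundary knots")
  }
  structure(list(
    degree = degree,
    interior_knots = interior_knots,
    boundary_knots = boundary_knots,
    knots_aug = c(rep(boundary_knots[1L], degree + 1L), interior_knots,
                  rep(boundary_knots[2L], degree + 1L))
  ), class = "bspline_spec")
}

#' B-spline basis for the log baseline hazard
#'
#' Standard B-spline basis of the specified degree; rows sum to one
#' (partition of unity). The baseline hazard is never evaluated outside
#' follow-up, so times outside the boundary knots are an error.
#'
#' @param times numeric vector within the boundary knots.
#' @param spec a [bspline_spec()].
#' @return matrix, `length(times)` rows, `Q + degree + 1` columns.
#' @export
bspline_basis <- function(times, spec) {
  stopifnot(inherits(spec, "bspline_spec"))
  times <- as.numeric(times)
  if (any(!is.finite(times))) stop("times must be finite")
  if (any(times < spec$boundary_knots[1L] | times > spec$boundary_knots[2L]))
    stop("times outside the baseline-hazard support [",
         spec$boundary_knots[1L], ", ", spec$boundary_knots[2L], "]")
  nb <- length(spec$knots_aug) - spec$degree - 1L
  if (!length(times)) return(matrix(0, 0L, nb))
  splines::splineDesign(spec$knots_aug, x = times, ord = spec$degree + 1L)
}

# design matrix for log h0(t): explicit intercept + B-spline columns with the
# first dropped (the full basis sums to 1, so one column is redundant given
# the intercept)
.baseline_design <- function(times, spec) {
  B <- bspline_basis(times, spec)
  if (!nrow(B)) return(B)
  cbind(1, B[, -1L, drop = FALSE])
}
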