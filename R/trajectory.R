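#' Trajectory model parameters
#'
#' Parameters of the longitudinal sub-model for square-root CD4 count:
#' subject i's true trajectory is
#' \deqn{m_i(t) = (\beta_0 + b_{i0}) + (\beta_1 + b_{i1}) B_1(t) +
#'   (\beta_2 + b_{i2}) B_2(t)}
#' with natural-cubic-spline basis functions `B_k`, random effects
#' `b_i ~ N(0, D)` and i.i.d. residual noise with variance `sigma2_eps`.
#'
#' @param beta numeric fixed effects, length `K + 2` (intercept plus one per
#'   basis column); sqrt-cells scale.
#' @param D random-effects covariance matrix, symmetric positive definite,
#'   same dimension as `beta`.
#' @param sigma2_eps residual variance, > 0.
#' @return object of class `trajectory_params`.
#' @export
trajectory_params <- function(beta, D, sigma2_eps) {
  beta <- as.numeric(beta)
  D <- as.matrix(D)
  if (!isTRUE(all.equal(D, t(D))) ||
      inherits(try(chol(D), silent = TRUE), "try-error"))
    stop("D must be symmetric positive definite")
  if (nrow(D) != length(beta)) stop("dim(D) must match length(beta)")
  if (!is.numeric(sigma2_eps) || sigma2_eps <= 0)
    stop("sigma2_eps must be > 0")
  structure(list(beta = beta, D = D, sigma2_eps = sigma2_eps),
            class = "trajectory_params")
}

#' Normal weight function for the weighted cumulative effect
#'
#' @param sigma_w positive scale (months) controlling how fast weights decay
#'   with elapsed time.
#' @param t_max upper limit (months) of the normalising integral; the
#'   dataset's maximum follow-up time, shared by all subjects.
#' @return object of class `weight_spec`.
#' @export
weight_spec <- function(sigma_w, t_max) {
  if (!is.numeric(sigma_w) || length(sigma_w) != 1L || sigma_w <= 0)
    stop("sigma_w must be a positive scalar")
  if (!is.numeric(t_max) || length(t_max) != 1L || t_max <= 0)
    stop("t_max must be a positive scalar")
  structure(list(sigma_w = sigma_w, t_max = t_max), class = "weight_spec")
}

#' Standardised normal weight
#'
#' The half-normal kernel `exp(-u^2 / 2 sigma_w^2)` normalised so that it
#' integrates to one over `[0, t_max]`. Elapsed times outside `[0, t_max]`
#' receive weight zero (the positive-part convention for `t - s`).
#'
#' @param u elapsed time since exposure (months), vectorised.
#' @param w a [weight_spec()].
#' @return weight density values (1/months).
#' @export
weight_fn <- function(u, w) {
  stopifnot(inherits(w, "weight_spec"))
  u <- as.numeric(u)
  z <- stats::pnorm(w$t_max, 0, w$sigma_w) - 0.5
  out <- stats::dnorm(u, 0, w$sigma_w) / z
  out[u < 0 | u > w$t_max] <- 0
  out
}

.traj_coef <- function(params, effects) {
  b <- if (is.list(effects)) effects$b else effects
  params$beta + as.numeric(b)
}

#' Trajectory functionals
#'
#' The four functionals of the true (noise-free) trajectory that can enter
#' the hazard: `m_value()` the current level, `m_slope()` its rate of change,
#' `m_area()` the area under the trajectory from 0 to `t`, and
#' `m_weighted_area()` the normal-kernel weighted area
#' \eqn{\int_0^t \varpi(t - s)\, m_i(s)\, ds}.
#'
#' `m_value`, `m_slope` and `m_area` are closed-form in the spline basis;
#' the weighted area has no closed form and uses 15-point Gauss-Legendre
#' quadrature on `[0, t]`, subdivided into 4 panels when `sigma_w < t / 10`
#' so a concentrated kernel is still resolved.
#'
#' @param t evaluation times (months), vectorised.
#' @param params a [trajectory_params()].
#' @param effects subject random effects: numeric vector `b` (or a list with
#'   element `b`) matching `length(params$beta)`.
#' @param ncs an [ncs_spec()].
#' @param w a [weight_spec()] (weighted area only).
#' @return numeric vector, one value per time.
#' @export
m_value <- function(t, params, effects, ncs) {
  drop(cbind(1, ncs_basis(t, ncs)) %*% .traj_coef(params, effects))
}

#' @rdname m_value
#' @export
m_slope <- function(t, params, effects, ncs) {
  drop(cbind(0, ncs_basis_deriv(t, ncs)) %*% .traj_coef(params, effects))
}

#' @rdname m_value
#' @export
m_area <- function(t, params, effects, ncs) {
  if (any(t < 0)) stop("m_area requires t >= 0")
  drop(cbind(t, ncs_basis_integral(t, ncs)) %*% .traj_coef(params, effects))
}

#' @rdname m_value
#' @export
m_weighted_area <- function(t, params, effects, ncs, w) {
  stopifnot(inherits(w, "weight_spec"))
  if (any(t < 0)) stop("m_weighted_area requires t >= 0")
  cf <- .traj_coef(params, effects)
  vapply(as.numeric(t), function(ti) {
    if (ti == 0) return(0)
    # integrate in elapsed time u = t - s with 15-point Gauss-Legendre per
    # panel; for concentrated kernels the panels are graded towards u = 0
    # (edges at multiples of sigma_w) so the kernel peak is always resolved
    if (w$sigma_w < ti / 10) {
      edges <- unique(pmin(c(0, 3, 10, 30, 100) * w$sigma_w, ti))
      if (max(edges) < ti) edges <- c(edges, ti)
    } else {
      edges <- c(0, ti)
    }
    tot <- 0
    for (e in seq_len(length(edges) - 1L)) {
      q <- gauss_legendre(15L, edges[e], edges[e + 1L])
      mv <- drop(cbind(1, ncs_basis(ti - q$nodes, ncs)) %*% cf)
      tot <- tot + sum(q$weights * weight_fn(q$nodes, w) * mv)
    }
    tot
  }, numeric(1L))
}

#' Longitudinal log-likelihood
#'
#' Gaussian log-density of the observed square-root CD4 measurements around
#' each subject's true trajectory, conditional on the random effects; full
#' normalising constants included.
#'
#' @param dataset a [trial_dataset()].
#' @param params a [trajectory_params()].
#' @param effects_all numeric matrix of random effects, one row per subject
#'   (rows in the order of `dataset$survival$subject_id`).
#' @param ncs an [ncs_spec()].
#' @return scalar log-likelihood.
#' @export
longitudinal_loglik <- function(dataset, params, effects_all, ncs) {
  long <- dataset$longitudinal
  if (any(!is.finite(long$y))) stop("non-finite longitudinal measurements")
  effects_all <- as.matrix(effects_all)
  idx <- match(long$subject_id, dataset$survival$subject_id)
  X <- cbind(1, ncs_basis(long$time, ncs))
  cf <- sweep(effects_all, 2L, params$beta, "+")
  mu <- rowSums(X * cf[idx, , drop = FALSE])
  sum(stats::dnorm(long$y, mu, sqrt(params$sigma2_eps), log = TRUE))
}
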