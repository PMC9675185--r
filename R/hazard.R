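#' Association structure between trajectory and hazard
#'
#' Chooses the functional through which the true square-root CD4 trajectory
#' enters the relative-risk model:
#' * `current_value`: hazard at t depends on `m_i(t)`;
#' * `slopes`: on `m_i(t)` and its derivative (level and velocity);
#' * `cumulative`: on the area under the trajectory up to t;
#' * `weighted_cumulative`: on a normal-kernel weighted area, recent values
#'   up-weighted, kernel scale estimated from the data.
#'
#' @param tag one of `"current_value"`, `"slopes"`, `"cumulative"`,
#'   `"weighted_cumulative"`.
#' @param weight a [weight_spec()]; required exactly when
#'   `tag = "weighted_cumulative"`.
#' @return object of class `assoc_structure`.
#' @export
assoc_structure <- function(tag = c("current_value", "slopes", "cumulative",
                                    "weighted_cumulative"),
                            weight = NULL) {
  tag <- match.arg(tag)
  if (tag == "weighted_cumulative") {
    if (!inherits(weight, "weight_spec"))
      stop("weighted_cumulative requires a weight_spec")
  } else if (!is.null(weight)) {
    stop("weight is only meaningful for the weighted_cumulative structure")
  }
  structure(list(tag = tag, weight = weight), class = "assoc_structure")
}

#' Survival sub-model parameters
#'
#' @param gamma length-3 numeric: log hazard ratios for (arm, age, gender).
#' @param alpha1 association coefficient (alpha, or alpha1 for the slopes
#'   structure).
#' @param alpha2 slope association coefficient; present exactly when the
#'   structure is `slopes`.
#' @param k baseline log-hazard coefficients: intercept `k0` followed by the
#'   B-spline column coefficients (see [bspline_spec()]).
#' @param sigma_w optional weight-kernel scale; when supplied it overrides
#'   the scale in the structure's [weight_spec()] (used while the scale is
#'   being estimated).
#' @return object of class `survival_params`.
#' @export
survival_params <- function(gamma, alpha1, alpha2 = NULL, k,
                            sigma_w = NULL) {
  gamma <- as.numeric(gamma)
  if (length(gamma) != 3L) stop("gamma must have length 3 (arm, age, gender)")
  if (!all(is.finite(c(gamma, alpha1, alpha2, k))))
    stop("survival parameters must be finite")
  structure(list(gamma = gamma, alpha1 = as.numeric(alpha1),
                 alpha2 = if (!is.null(alpha2)) as.numeric(alpha2),
                 k = as.numeric(k), sigma_w = sigma_w),
            class = "survival_params")
}

.check_structure_params <- function(structure, surv_params) {
  if (structure$tag == "slopes" && is.null(surv_params$alpha2))
    stop("slopes structure requires alpha2")
  if (structure$tag != "slopes" && !is.null(surv_params$alpha2))
    stop("alpha2 is only meaningful for the slopes structure")
}

.effective_weight <- function(structure, surv_params) {
  w <- structure$weight
  if (!is.null(surv_params$sigma_w)) w$sigma_w <- surv_params$sigma_w
  w
}

#' Log hazard under an association structure
#'
#' \deqn{\log h_i(t) = \log h_0(t) + \gamma_1 Arm_i + \gamma_2 Age_i +
#'   \gamma_3 Gender_i + f\{m_i(\cdot); \alpha\}}
#' with `f` the chosen association functional and the log baseline hazard a
#' B-spline expansion.
#'
#' @param t times (months), within the baseline-spline support; vectorised.
#' @param structure an [assoc_structure()].
#' @param surv_params a [survival_params()].
#' @param traj_params a [trajectory_params()].
#' @param effects subject random effects (vector `b`).
#' @param covs list or one-row data.frame with `arm`, `age`, `gender`.
#' @param bspec a [bspline_spec()].
#' @param ncs an [ncs_spec()].
#' @return log hazard (per month), one value per time.
#' @export
log_hazard <- function(t, structure, surv_params, traj_params, effects,
                       covs, bspec, ncs) {
  stopifnot(inherits(structure, "assoc_structure"),
            inherits(surv_params, "survival_params"))
  .check_structure_params(structure, surv_params)
  lh0 <- drop(.baseline_design(t, bspec) %*% surv_params$k)
  wterm <- sum(surv_params$gamma * c(covs$arm, covs$age, covs$gender))
  assoc <- switch(structure$tag,
    current_value = surv_params$alpha1 *
      m_value(t, traj_params, effects, ncs),
    slopes = surv_params$alpha1 * m_value(t, traj_params, effects, ncs) +
      surv_params$alpha2 * m_slope(t, traj_params, effects, ncs),
    cumulative = surv_params$alpha1 * m_area(t, traj_params, effects, ncs),
    weighted_cumulative = surv_params$alpha1 *
      m_weighted_area(t, traj_params, effects, ncs,
                      .effective_weight(structure, surv_params))
  )
  lh0 + wterm + assoc
}

#' Cumulative hazard
#'
#' \eqn{H_i(T) = \int_0^T h_i(s) ds} by panelised 15-point Gauss-Legendre
#' quadrature (7 panels when `T > 12` months, matching the spacing of the
#' baseline-spline knots over long follow-up).
#'
#' @param T nonnegative time (months), within the baseline-spline support.
#' @inheritParams log_hazard
#' @return scalar cumulative hazard (dimensionless).
#' @export
cumulative_hazard <- function(T, structure, surv_params, traj_params,
                              effects, covs, bspec, ncs) {
  if (length(T) != 1L || T < 0) stop("T must be a nonnegative scalar")
  if (T > bspec$boundary_knots[2L] + 1e-8)
    stop("T beyond the baseline-hazard support")
  if (T == 0) return(0)
  q <- gauss_legendre_panels(15L, 0, T, panels = if (T > 12) 7L else 1L)
  sum(q$weights * exp(log_hazard(q$nodes, structure, surv_params,
                                 traj_params, effects, covs, bspec, ncs)))
}

#' Survival log-likelihood (conditional on random effects)
#'
#' \eqn{\sum_i \delta_i \log h_i(T_i) - H_i(T_i)}.
#'
#' @param dataset a [trial_dataset()].
#' @param structure an [assoc_structure()].
#' @param surv_params a [survival_params()].
#' @param traj_params a [trajectory_params()].
#' @param effects_all matrix of random effects, one row per subject in the
#'   order of `dataset$survival`.
#' @param bspec,ncs basis specifications.
#' @return scalar log-likelihood.
#' @export
survival_loglik <- function(dataset, structure, surv_params, traj_params,
                            effects_all, bspec, ncs) {
  s <- dataset$survival
  if (any(s$time < 0)) stop("negative survival times")
  effects_all <- as.matrix(effects_all)
  ll <- 0
  for (i in seq_len(nrow(s))) {
    covs <- list(arm = s$arm[i], age = s$age[i], gender = s$gender[i])
    H <- cumulative_hazard(s$time[i], structure, surv_params, traj_params,
                           effects_all[i, ], covs, bspec, ncs)
    lh <- if (s$event[i] == 1)
      log_hazard(s$time[i], structure, surv_params, traj_params,
                 effects_all[i, ], covs, bspec, ncs) else 0
    ll <- ll + s$event[i] * lh - H
  }
  ll
}

# multivariate normal log density, rows of x
.dmvnorm_log <- function(x, D) {
  x <- as.matrix(x)
  U <- chol(D)
  z <- forwardsolve(t(U), t(x))
  -0.5 * ncol(x) * log(2 * pi) - sum(log(diag(U))) - 0.5 * colSums(z^2)
}

#' Joint log-likelihood of the shared-random-effects model
#'
#' Longitudinal Gaussian likelihood + survival likelihood + random-effects
#' density, all conditional on the subject-specific effects `b_i` (the two
#' sub-models share the `b_i`; marginalisation over them is done by MCMC).
#'
#' @inheritParams survival_loglik
#' @return scalar log-density.
#' @export
joint_loglik <- function(dataset, structure, surv_params, traj_params,
                         effects_all, bspec, ncs) {
  effects_all <- as.matrix(effects_all)
  longitudinal_loglik(dataset, traj_params, effects_all, ncs) +
    survival_loglik(dataset, structure, surv_params, traj_params,
                    effects_all, bspec, ncs) +
    sum(.dmvnorm_log(effects_all, traj_params$D))
}
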