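#' Trial design for the synthetic-data generator
#'
#' Design of the emulated HIV/TB treatment-timing trial: 642 subjects, 2:1
#' allocation to the combined integrated therapy arms, mean age 34.2 (SD 8.3)
#' years truncated at 18, 49.7% male, CD4 visits at 0, 2, 6, 12, 18 and 24
#' months, administrative censoring at 60 months and independent exponential
#' dropout.
#'
#' @param n_subjects number of subjects.
#' @param arm_allocation probability of the integrated arm.
#' @param age_mean,age_sd age distribution (years), truncated at 18.
#' @param p_male probability of male sex (`gender = 0`).
#' @param visit_times scheduled CD4 visit times (months), starting at 0,
#'   strictly increasing.
#' @param admin_censor_time administrative censoring time (months).
#' @param dropout_rate per-month exponential dropout rate (non-informative).
#' @param seed integer RNG seed used by [simulate_trial()].
#' @return object of class `trial_design`.
#' @export
trial_design <- function(n_subjects = 642L, arm_allocation = 2 / 3,
                         age_mean = 34.2, age_sd = 8.3, p_male = 0.497,
                         visit_times = c(0, 2, 6, 12, 18, 24),
                         admin_censor_time = 60, dropout_rate = 0.035,
                         seed = 20220642L) {
  if (arm_allocation < 0 || arm_allocation > 1 || p_male < 0 || p_male > 1)
    stop("probabilities must be in [0, 1]")
  if (visit_times[1L] != 0 || is.unsorted(visit_times, strictly = TRUE))
    stop("visit_times must start at 0 and be strictly increasing")
  if (admin_censor_time <= 0 || dropout_rate < 0 || n_subjects < 1)
    stop("invalid design")
  structure(list(n_subjects = as.integer(n_subjects),
                 arm_allocation = arm_allocation, age_mean = age_mean,
                 age_sd = age_sd, p_male = p_male,
                 visit_times = visit_times,
                 admin_censor_time = admin_censor_time,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "trial_design")
}

#' Draw baseline covariates
#'
#' Arm is Bernoulli(`arm_allocation`); age is normal truncated at 18 years;
#' gender is Bernoulli(1 - `p_male`) with 1 = women. Uses the current RNG
#' state (seed it for reproducibility).
#'
#' @param design a [trial_design()].
#' @return data.frame with columns `arm`, `age`, `gender`.
#' @export
draw_covariates <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  n <- design$n_subjects
  arm <- stats::rbinom(n, 1L, design$arm_allocation)
  age <- stats::rnorm(n, design$age_mean, design$age_sd)
  while (any(age < 18))
    age[age < 18] <- stats::rnorm(sum(age < 18), design$age_mean,
                                  design$age_sd)
  gender <- stats::rbinom(n, 1L, 1 - design$p_male)
  data.frame(arm = arm, age = age, gender = gender)
}

# grid-constant matrices shared by every subject of a simulated trial
.sim_grid_cache <- function(structure, surv_params, bspec, ncs, t_hi,
                            grid_points = 1201L) {
  tt <- seq(0, t_hi, length.out = grid_points)
  cache <- list(tt = tt,
                base = drop(.baseline_design(tt, bspec) %*% surv_params$k),
                Xv = cbind(1, ncs_basis(tt, ncs)))
  if (structure$tag == "slopes")
    cache$Xd <- cbind(0, ncs_basis_deriv(tt, ncs))
  if (structure$tag == "cumulative")
    cache$Xi <- cbind(tt, ncs_basis_integral(tt, ncs))
  if (structure$tag == "weighted_cumulative") {
    w <- .effective_weight(structure, surv_params)
    h <- tt[2L] - tt[1L]
    K <- .wkernel(outer(tt, tt, "-"), w$sigma_w, w$t_max) * h
    K[, 1L] <- K[, 1L] / 2 # trapezoid end weights
    diag(K) <- diag(K) / 2
    cache$K <- K
  }
  cache
}

# cumulative hazard of one subject tabulated on a dense grid
.hazard_grid <- function(structure, surv_params, traj_params, effects, covs,
                         bspec, ncs, t_hi, grid_points = 1201L,
                         sim_cache = NULL) {
  if (is.null(sim_cache))
    sim_cache <- .sim_grid_cache(structure, surv_params, bspec, ncs, t_hi,
                                 grid_points)
  tt <- sim_cache$tt
  cf <- .traj_coef(traj_params, effects)
  a1 <- surv_params$alpha1
  assoc <- switch(structure$tag,
    current_value = a1 * drop(sim_cache$Xv %*% cf),
    slopes = a1 * drop(sim_cache$Xv %*% cf) +
      surv_params$alpha2 * drop(sim_cache$Xd %*% cf),
    cumulative = a1 * drop(sim_cache$Xi %*% cf),
    weighted_cumulative = a1 * drop(sim_cache$K %*% (sim_cache$Xv %*% cf)))
  lh <- sim_cache$base +
    sum(surv_params$gamma * c(covs$arm, covs$age, covs$gender)) + assoc
  h <- exp(lh)
  H <- c(0, cumsum((h[-1L] + h[-length(tt)]) / 2) * diff(tt))
  list(tt = tt, H = H)
}

#' Simulate one event time by inverting the cumulative hazard
#'
#' Draws `U ~ Uniform(0, 1)` and solves `H_i(T) = -log U` by bracketed root
#' finding on a dense tabulation of the subject's cumulative hazard (1201
#' grid points over the censoring horizon). If the cumulative hazard never
#' reaches `-log U` before administrative censoring, or exponential dropout
#' comes first, the subject is censored at the earlier of those times.
#'
#' @param traj_params,effects,covs subject-level trajectory parameters,
#'   random effects and covariates.
#' @param structure,surv_params hazard model.
#' @param bspec,ncs basis specifications.
#' @param admin_censor_time administrative censoring time (months).
#' @param dropout_rate per-month exponential dropout rate (0 = none).
#' @param grid an optional precomputed `.hazard_grid()` (reused across draws
#'   for the same subject).
#' @return list with `time` (months) and `event` (0/1).
#' @export
simulate_event_time <- function(traj_params, effects, covs, structure,
                                surv_params, bspec, ncs,
                                admin_censor_time, dropout_rate = 0,
                                grid = NULL) {
  if (is.null(grid))
    grid <- .hazard_grid(structure, surv_params, traj_params, effects, covs,
                         bspec, ncs, admin_censor_time)
  target <- -log(stats::runif(1L))
  if (!all(is.finite(grid$H)))
    stop("non-finite cumulative hazard during event-time simulation; ",
         "check the generating parameters")
  cens <- if (dropout_rate > 0)
    min(stats::rexp(1L, dropout_rate), admin_censor_time)
  else admin_censor_time
  if (target >= grid$H[length(grid$H)]) # no root below the horizon
    return(list(time = cens, event = 0L))
  j <- findInterval(target, grid$H) # bracket: H[j] <= target < H[j + 1]
  t_ev <- grid$tt[j] + (target - grid$H[j]) /
    (grid$H[j + 1L] - grid$H[j]) * (grid$tt[j + 1L] - grid$tt[j])
  if (t_ev <= cens) list(time = t_ev, event = 1L)
  else list(time = cens, event = 0L)
}

#' Default generating scenario
#'
#' One documented set of generating parameters per association structure,
#' emulating the trial the package targets: square-root CD4 starting near 12
#' (CD4 about 145 cells/mm3) and recovering towards 16 by 24 months, a
#' declining baseline hazard concentrating deaths in the first year, hazard
#' ratios near 0.6 for the integrated arm and for women, and an association
#' coefficient calibrated (together with the baseline level) so the marginal
#' death fraction is close to 10.7%.
#'
#' @param structure_tag which association structure generates the data.
#' @param arm_effect_on_trajectory if `TRUE`, integrated-arm subjects get a
#'   faster CD4 recovery (adds a deliberate misspecification stressor: the
#'   longitudinal model fitted by this package has no covariates).
#' @return list with `traj_params`, `structure`, `surv_params`, `ncs`,
#'   `bspec`, and `arm_traj_shift`.
#' @export
default_scenario <- function(structure_tag = c("cumulative", "current_value",
                                               "slopes",
                                               "weighted_cumulative"),
                             arm_effect_on_trajectory = FALSE) {
  structure_tag <- match.arg(structure_tag)
  ncs <- ncs_spec(c(0, 24), 9)
  bspec <- bspline_spec(c(0, 60), c(10, 20, 30, 40, 50), degree = 3L)
  # fixed effects: m(0) = 12, m(9) ~ 14.3, m(24) ~ 16 (sqrt-CD4 recovery)
  Bk <- ncs_basis(c(9, 24), ncs)
  beta <- c(12, solve(Bk, c(14.3, 16) - 12))
  sds <- c(3.5, 2, 2)
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- -0.2
  R[1, 3] <- R[3, 1] <- 0.1
  R[2, 3] <- R[3, 2] <- -0.1
  D <- diag(sds) %*% R %*% diag(sds)
  traj <- trajectory_params(beta = beta, D = D, sigma2_eps = 2)

  wspec <- weight_spec(sigma_w = 6, t_max = 60)
  structure <- assoc_structure(structure_tag,
                               weight = if (structure_tag ==
                                            "weighted_cumulative") wspec)
  alpha1 <- switch(structure_tag, current_value = -0.2, slopes = -0.2,
                   cumulative = -0.0035, weighted_cumulative = -0.2)
  alpha2 <- if (structure_tag == "slopes") 0.05
  # declining baseline: deaths concentrate in the first 12 months; the
  # offset per structure compensates the mean association term so the
  # marginal death fraction lands near 10.7%
  offset <- switch(structure_tag, current_value = 1.95, slopes = 2.0,
                   cumulative = -0.2, weighted_cumulative = 0.6)
  tt <- seq(0, 60, length.out = 241L)
  shape <- log(0.05 * exp(-tt / 10) + 0.004) + offset
  Xb <- .baseline_design(tt, bspec)
  k <- qr.solve(Xb, shape)
  sp <- survival_params(gamma = c(log(0.6), -0.01, log(0.6)),
                        alpha1 = alpha1, alpha2 = alpha2, k = k)
  list(traj_params = traj, structure = structure, surv_params = sp,
       ncs = ncs, bspec = bspec,
       arm_traj_shift = if (arm_effect_on_trajectory) c(0, 1, 2) else
         c(0, 0, 0))
}

#' Simulate a complete synthetic trial
#'
#' Per subject: draw covariates and random effects `b_i ~ N(0, D)`, simulate
#' the death time from the exact generating hazard by inverse-CDF sampling,
#' apply dropout and administrative censoring, then record square-root CD4
#' at every scheduled visit not later than the follow-up time with residual
#' noise `N(0, sigma2_eps)`. Deterministic given `design$seed`.
#'
#' @param design a [trial_design()].
#' @param scenario a generating scenario, see [default_scenario()].
#' @return a [trial_dataset()] whose `meta` records the seed and the true
#'   generating parameters.
#' @export
simulate_trial <- function(design = trial_design(),
                           scenario = default_scenario()) {
  stopifnot(inherits(design, "trial_design"))
  set.seed(design$seed)
  n <- design$n_subjects
  covs <- draw_covariates(design)
  U <- chol(scenario$traj_params$D)
  b <- matrix(stats::rnorm(3L * n), n, 3L) %*% U
  surv <- data.frame(subject_id = seq_len(n), time = NA_real_,
                     event = NA_integer_, arm = covs$arm, age = covs$age,
                     gender = covs$gender)
  gcache <- .sim_grid_cache(scenario$structure, scenario$surv_params,
                            scenario$bspec, scenario$ncs,
                            design$admin_censor_time)
  long_list <- vector("list", n)
  for (i in seq_len(n)) {
    eff <- b[i, ] + covs$arm[i] * scenario$arm_traj_shift
    grid_i <- .hazard_grid(scenario$structure, scenario$surv_params,
                           scenario$traj_params, eff, covs[i, ],
                           scenario$bspec, scenario$ncs,
                           design$admin_censor_time, sim_cache = gcache)
    et <- simulate_event_time(scenario$traj_params, eff, covs[i, ],
                              scenario$structure, scenario$surv_params,
                              scenario$bspec, scenario$ncs,
                              design$admin_censor_time, design$dropout_rate,
                              grid = grid_i)
    surv$time[i] <- et$time
    surv$event[i] <- et$event
    vt <- design$visit_times[design$visit_times <= et$time]
    y <- m_value(vt, scenario$traj_params, eff, scenario$ncs) +
      stats::rnorm(length(vt), 0, sqrt(scenario$traj_params$sigma2_eps))
    long_list[[i]] <- data.frame(subject_id = i, time = vt, y = y)
  }
  trial_dataset(do.call(rbind, long_list), surv,
                meta = list(seed = design$seed,
                            t_max = design$admin_censor_time,
                            truth = list(
                              beta = scenario$traj_params$beta,
                              D = scenario$traj_params$D,
                              sigma2_eps = scenario$traj_params$sigma2_eps,
                              gamma = scenario$surv_params$gamma,
                              alpha1 = scenario$surv_params$alpha1,
                              alpha2 = scenario$surv_params$alpha2,
                              structure = scenario$structure$tag)))
}
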