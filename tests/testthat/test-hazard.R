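flat_baseline <- function(bspec, level = log(0.05)) {
  # constant log baseline hazard: intercept only, spline columns zero
  c(level, rep(0, ncol(jmassoc:::.baseline_design(0, bspec)) - 1L))
}

hz_fixture <- function() {
  ds <- sim_fixture()
  sp <- fixture_specs(ds)
  list(ds = ds, ncs = sp$ncs, bspec = sp$bspec,
       tp = trajectory_params(c(12, 3, 2), diag(c(9, 2, 2)), 1.5),
       covs = list(arm = 1, age = 35, gender = 0))
}

test_that("null association reduces the log hazard to baseline + covariates", {
  fx <- hz_fixture()
  k <- flat_baseline(fx$bspec)
  tt <- c(0.5, 6, 20, 40)
  for (tag in c("current_value", "cumulative")) {
    st <- assoc_structure(tag)
    sp <- survival_params(c(0, 0, 0), alpha1 = 0, k = k)
    expect_equal(log_hazard(tt, st, sp, fx$tp, c(1, -1, 2), fx$covs,
                            fx$bspec, fx$ncs),
                 rep(log(0.05), 4), tolerance = 1e-12)
  }
  st <- assoc_structure("slopes")
  sp <- survival_params(c(0, 0, 0), alpha1 = 0, alpha2 = 0, k = k)
  expect_equal(log_hazard(tt, st, sp, fx$tp, c(1, -1, 2), fx$covs,
                          fx$bspec, fx$ncs), rep(log(0.05), 4))
})

test_that("slopes structure with alpha2 = 0 equals current value everywhere", {
  fx <- hz_fixture()
  set.seed(8)
  k <- rnorm(9, -2, 0.5)
  b <- rnorm(3, 0, 0.6)
  tt <- seq(0.2, 55, length.out = 40)
  cv <- log_hazard(tt, assoc_structure("current_value"),
                   survival_params(c(-0.4, -0.01, -0.3), alpha1 = -0.15,
                                   k = k),
                   fx$tp, b, fx$covs, fx$bspec, fx$ncs)
  sl <- log_hazard(tt, assoc_structure("slopes"),
                   survival_params(c(-0.4, -0.01, -0.3), alpha1 = -0.15,
                                   alpha2 = 0, k = k),
                   fx$tp, b, fx$covs, fx$bspec, fx$ncs)
  expect_identical(cv, sl)
})

test_that("log hazard recomposes from the trajectory functionals", {
  fx <- hz_fixture()
  set.seed(9)
  k <- rnorm(9, -2, 0.4)
  b <- rnorm(3, 0, 0.5)
  gm <- c(-0.5, -0.01, -0.4)
  tt <- c(1, 7, 19, 33.5)
  base <- drop(jmassoc:::.baseline_design(tt, fx$bspec) %*% k)
  wterm <- sum(gm * c(1, 35, 0))
  w <- weight_spec(5, fx$ds$meta$t_max)
  cases <- list(
    list(st = assoc_structure("current_value"),
         sp = survival_params(gm, -0.2, k = k),
         f = m_value(tt, fx$tp, b, fx$ncs) * -0.2),
    list(st = assoc_structure("slopes"),
         sp = survival_params(gm, -0.2, alpha2 = 0.3, k = k),
         f = -0.2 * m_value(tt, fx$tp, b, fx$ncs) +
           0.3 * m_slope(tt, fx$tp, b, fx$ncs)),
    list(st = assoc_structure("cumulative"),
         sp = survival_params(gm, -0.004, k = k),
         f = -0.004 * m_area(tt, fx$tp, b, fx$ncs)),
    list(st = assoc_structure("weighted_cumulative", w),
         sp = survival_params(gm, -0.2, k = k),
         f = -0.2 * m_weighted_area(tt, fx$tp, b, fx$ncs, w)))
  for (cs in cases)
    expect_equal(log_hazard(tt, cs$st, cs$sp, fx$tp, b, fx$covs, fx$bspec,
                            fx$ncs),
                 base + wterm + cs$f, tolerance = 1e-12)
})

test_that("structure/parameter mismatches are configuration errors", {
  fx <- hz_fixture()
  k <- flat_baseline(fx$bspec)
  expect_error(assoc_structure("weighted_cumulative"), "weight_spec")
  expect_error(assoc_structure("current_value", weight_spec(5, 30)),
               "only meaningful")
  sp_no2 <- survival_params(c(0, 0, 0), alpha1 = -0.1, k = k)
  expect_error(log_hazard(1, assoc_structure("slopes"), sp_no2, fx$tp,
                          c(0, 0, 0), fx$covs, fx$bspec, fx$ncs),
               "alpha2")
  sp_extra <- survival_params(c(0, 0, 0), alpha1 = -0.1, alpha2 = 0.2,
                              k = k)
  expect_error(log_hazard(1, assoc_structure("current_value"), sp_extra,
                          fx$tp, c(0, 0, 0), fx$covs, fx$bspec, fx$ncs),
               "slopes")
})

test_that("cumulative hazard: H(0) = 0, constant-hazard closed form, trapezoid oracle", {
  fx <- hz_fixture()
  st <- assoc_structure("current_value")
  spar <- survival_params(c(0, 0, 0), alpha1 = 0, k = flat_baseline(fx$bspec))
  args <- list(st, spar, fx$tp, c(0, 0, 0), fx$covs, fx$bspec, fx$ncs)
  expect_equal(do.call(cumulative_hazard, c(0, args)), 0)
  expect_equal(do.call(cumulative_hazard, c(31, args)), 0.05 * 31,
               tolerance = 1e-10)
  expect_error(do.call(cumulative_hazard, c(fx$ds$meta$t_max + 5, args)),
               "support")
  # random configuration vs dense trapezoid
  set.seed(10)
  spar2 <- survival_params(c(-0.4, -0.01, -0.2), alpha1 = -0.15,
                           k = rnorm(9, -2, 0.4))
  b <- rnorm(3, 0, 0.5)
  g <- seq(0, 24, length.out = 1e5 + 1)
  hv <- exp(log_hazard(g, st, spar2, fx$tp, b, fx$covs, fx$bspec, fx$ncs))
  trap <- sum((hv[-1] + hv[-length(g)]) / 2) * 24 / 1e5
  H <- cumulative_hazard(24, st, spar2, fx$tp, b, fx$covs, fx$bspec, fx$ncs)
  expect_equal(H, trap, tolerance = 1e-5)
})

test_that("cumulative hazard is nonnegative and nondecreasing for all structures", {
  fx <- hz_fixture()
  set.seed(12)
  k <- rnorm(9, -2.5, 0.3)
  b <- rnorm(3, 0, 0.5)
  w <- weight_spec(6, fx$ds$meta$t_max)
  Ts <- seq(0, 55, by = 5)
  for (tag in c("current_value", "slopes", "cumulative",
                "weighted_cumulative")) {
    st <- assoc_structure(tag, if (tag == "weighted_cumulative") w)
    sp <- survival_params(c(-0.3, -0.01, -0.2),
                          alpha1 = if (tag == "cumulative") -0.003 else -0.1,
                          alpha2 = if (tag == "slopes") 0.1, k = k)
    H <- vapply(Ts, function(T)
      cumulative_hazard(T, st, sp, fx$tp, b, fx$covs, fx$bspec, fx$ncs),
      numeric(1))
    expect_true(all(H >= 0))
    expect_true(all(diff(H) >= 0))
  }
})

test_that("survival log-likelihood composes from hazard pieces", {
  # single subject, constant hazard, event at T: log h - h T
  long <- data.frame(subject_id = 1L, time = 0, y = 12)
  surv <- data.frame(subject_id = 1L, time = 7, event = 1L, arm = 0L,
                     age = 30, gender = 1L)
  ds <- trial_dataset(long, surv, meta = list(t_max = 10))
  ncs <- ncs_spec(c(0, 10), 5)
  bspec <- bspline_spec(c(0, 10), 5, degree = 3L)
  k <- flat_baseline(bspec, log(0.08))
  st <- assoc_structure("current_value")
  sp <- survival_params(c(0, 0, 0), alpha1 = 0, k = k)
  tp <- trajectory_params(c(12, 0, 0), diag(3), 1)
  expect_equal(survival_loglik(ds, st, sp, tp, matrix(0, 1, 3), bspec, ncs),
               log(0.08) - 0.08 * 7, tolerance = 1e-10)
  # all censored at ~0 follow-up: log-likelihood ~ 0
  surv0 <- data.frame(subject_id = 1:2, time = c(1e-9, 1e-9), event = 0L,
                      arm = 0L, age = 30, gender = 0L)
  long0 <- data.frame(subject_id = 1:2, time = 0, y = c(12, 11))
  ds0 <- trial_dataset(long0, surv0, meta = list(t_max = 10))
  expect_equal(survival_loglik(ds0, st, sp, tp, matrix(0, 2, 3), bspec, ncs),
               0, tolerance = 1e-9)
  # compositional oracle on a small random dataset
  fx <- hz_fixture()
  sub <- fx$ds$survival[1:8, ]
  sub_long <- fx$ds$longitudinal[fx$ds$longitudinal$subject_id %in%
                                   sub$subject_id, ]
  dss <- trial_dataset(sub_long, sub, meta = list(t_max = fx$ds$meta$t_max))
  set.seed(13)
  sp2 <- survival_params(c(-0.4, -0.01, -0.2), alpha1 = -0.1,
                         k = rnorm(9, -2, 0.3))
  b <- matrix(rnorm(24, 0, 0.5), 8, 3)
  ll <- survival_loglik(dss, st, sp2, fx$tp, b, fx$bspec, fx$ncs)
  oracle <- 0
  for (i in 1:8) {
    cv <- list(arm = sub$arm[i], age = sub$age[i], gender = sub$gender[i])
    H <- cumulative_hazard(sub$time[i], st, sp2, fx$tp, b[i, ], cv,
                           fx$bspec, fx$ncs)
    lh <- log_hazard(sub$time[i], st, sp2, fx$tp, b[i, ], cv, fx$bspec,
                     fx$ncs)
    oracle <- oracle + sub$event[i] * lh - H
  }
  expect_equal(ll, oracle, tolerance = 1e-12)
})

test_that("joint log-likelihood is the sum of its parts and factorises at alpha = 0", {
  ds <- tiny_dataset()
  ncs <- default_ncs_spec(ds)
  bspec <- bspline_spec(c(0, 10), 5, degree = 3L)
  tp <- trajectory_params(c(12, 2, 1), diag(c(4, 1, 1)), 1.3)
  st <- assoc_structure("current_value")
  set.seed(14)
  sp <- survival_params(c(-0.3, -0.01, -0.2), alpha1 = -0.12,
                        k = rnorm(5, -2, 0.3))
  b <- matrix(rnorm(6, 0, 0.6), 2, 3)
  jl <- joint_loglik(ds, st, sp, tp, b, bspec, ncs)
  parts <- longitudinal_loglik(ds, tp, b, ncs) +
    survival_loglik(ds, st, sp, tp, b, bspec, ncs) +
    sum(jmassoc:::.dmvnorm_log(b, tp$D))
  expect_equal(jl, parts, tolerance = 1e-12)
  # hand-composed oracle for the b-density part
  hand_b <- sum(dnorm(b[, 1], 0, 2, log = TRUE)) +
    sum(dnorm(b[, 2], 0, 1, log = TRUE)) + sum(dnorm(b[, 3], 0, 1, log = TRUE))
  expect_equal(sum(jmassoc:::.dmvnorm_log(b, tp$D)), hand_b,
               tolerance = 1e-12)
  # with alpha = 0 the survival part does not depend on b
  sp0 <- survival_params(c(-0.3, -0.01, -0.2), alpha1 = 0, k = sp$k)
  s1 <- survival_loglik(ds, st, sp0, tp, b, bspec, ncs)
  s2 <- survival_loglik(ds, st, sp0, tp, matrix(0, 2, 3), bspec, ncs)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("doubling the quadrature resolution barely changes the survival loglik", {
  fx <- hz_fixture()
  set.seed(15)
  b <- matrix(rnorm(nrow(fx$ds$survival) * 3, 0, 0.5),
              nrow(fx$ds$survival), 3)
  w <- weight_spec(6, fx$ds$meta$t_max)
  for (tag in c("current_value", "cumulative", "weighted_cumulative")) {
    st <- assoc_structure(tag, if (tag == "weighted_cumulative") w)
    sp <- survival_params(c(-0.4, -0.01, -0.2),
                          alpha1 = if (tag == "cumulative") -0.003 else -0.1,
                          k = rnorm(9, -2.5, 0.3))
    cache1 <- jmassoc:::build_surv_cache(fx$ds, st, fx$bspec, fx$ncs)
    ll1 <- sum(jmassoc:::surv_loglik_cached(
      cache1, sp$k, sp$gamma, sp$alpha1, NULL,
      matrix(fx$tp$beta, nrow(b), 3, byrow = TRUE) + b, 6))
    ll2 <- survival_loglik(fx$ds, st, sp, fx$tp, b, fx$bspec, fx$ncs)
    expect_equal(ll1, ll2, tolerance = 1e-6)
  }
})
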