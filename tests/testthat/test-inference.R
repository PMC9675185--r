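short_settings <- function(seed = 1L, ...) {
  mcmc_settings(n_chains = 1L, n_adapt = 200L, n_burnin = 100L,
                n_iter = 400L, seed = seed, ...)
}

test_that("initialization recovers truth on noiseless data and is always finite", {
  sc <- default_scenario("current_value")
  sc$traj_params$sigma2_eps <- 1e-20
  sc$traj_params$D <- diag(1e-20, 3)
  ds <- simulate_trial(trial_design(n_subjects = 40, seed = 3L), sc)
  init <- init_joint_model(ds, sc$structure, sc$ncs, sc$bspec)
  expect_equal(init$beta, sc$traj_params$beta, tolerance = 1e-5)
  # random dataset: finite joint loglik at the initial state
  ds2 <- sim_fixture()
  sp <- fixture_specs(ds2)
  init2 <- init_joint_model(ds2, assoc_structure("current_value"), sp$ncs,
                            sp$bspec)
  jl <- joint_loglik(ds2, assoc_structure("current_value"),
                     survival_params(init2$gamma, init2$alpha1,
                                     k = init2$k),
                     trajectory_params(init2$beta, init2$D,
                                       init2$sigma2_eps),
                     init2$b, sp$bspec, sp$ncs)
  expect_true(is.finite(jl))
})

test_that("initialization handles degenerate inputs as documented", {
  # no events: gamma and k fall back to prior-mean-style values
  ds <- sim_fixture()
  ds0 <- ds
  ds0$survival$event <- 0L
  sp <- fixture_specs(ds)
  init <- init_joint_model(ds0, assoc_structure("current_value"), sp$ncs,
                           sp$bspec)
  expect_equal(init$gamma, c(0, 0, 0))
  expect_true(all(is.finite(init$k)))
  # fewer than 3 distinct measurement times
  long <- data.frame(subject_id = c(1L, 2L), time = c(0, 0), y = c(10, 12))
  surv <- data.frame(subject_id = 1:2, time = 5, event = 0L, arm = 0L,
                     age = 30, gender = 0L)
  ds_bad <- trial_dataset(long, surv)
  expect_error(init_joint_model(ds_bad, assoc_structure("current_value"),
                                sp$ncs, sp$bspec), "distinct measurement")
})

test_that("posterior of beta matches the Gaussian conjugate posterior when the survival part is off", {
  # fix everything except beta; likelihood reduces to a linear-Gaussian
  # model, so the posterior is available in closed form
  ds <- sim_fixture()
  sp <- fixture_specs(ds)
  n <- nrow(ds$survival)
  b_fix <- matrix(0, n, 3)
  sig2 <- 1.8
  fit <- fit_joint_model(
    ds, assoc_structure("current_value"),
    settings = mcmc_settings(n_chains = 2L, n_adapt = 400L, n_burnin = 200L,
                             n_iter = 2000L, seed = 42L),
    ncs = sp$ncs, bspec = sp$bspec, likelihood = "longitudinal",
    fix = list(b = b_fix, sigma2_eps = sig2, D = diag(3)))
  X <- cbind(1, ncs_basis(ds$longitudinal$time, sp$ncs))
  prec <- crossprod(X) / sig2 + diag(3) / 100
  Sig <- solve(prec)
  mu <- drop(Sig %*% crossprod(X, ds$longitudinal$y) / sig2)
  bd <- fit$draws[, c("beta0", "beta1", "beta2")]
  mc_se <- sqrt(diag(Sig)) / sqrt(200) # generous effective-sample bound
  expect_lt(max(abs(colMeans(bd) - mu) / sqrt(diag(Sig))), 0.2)
  expect_lt(max(abs(apply(bd, 2, sd) / sqrt(diag(Sig)) - 1)), 0.2)
})

test_that("prior-only sampling recovers prior moments (kernel validation)", {
  ds <- tiny_dataset()
  ncs <- default_ncs_spec(ds)
  bspec <- bspline_spec(c(0, 10), 5, degree = 3L)
  fit <- fit_joint_model(
    ds, assoc_structure("current_value"),
    settings = mcmc_settings(n_chains = 2L, n_adapt = 500L, n_burnin = 500L,
                             n_iter = 4000L, seed = 7L),
    ncs = ncs, bspec = bspec, likelihood = "none",
    init = list(beta = c(0, 0, 0), b = matrix(0, 2, 3), sigma2_eps = 1,
                D = diag(3), gamma = c(0, 0, 0), alpha1 = 0,
                k = rep(0, 5)))
  # coefficients have independent Normal(0, 100) priors
  bd <- fit$draws[, c("beta0", "gamma_arm", "alpha1", "k0")]
  expect_lt(max(abs(colMeans(bd))), 10 * 3 / sqrt(50)) # ~3 MC SEs, ESS >= 50
  expect_lt(max(abs(apply(bd, 2, sd) - 10) / 10), 0.35)
})

test_that("posterior mean of beta0 tracks truth in a low-noise smoke run", {
  sc <- default_scenario("current_value")
  sc$traj_params$sigma2_eps <- 0.05
  ds <- simulate_trial(trial_design(n_subjects = 120, seed = 9L), sc)
  fit <- fit_joint_model(ds, sc$structure, settings = short_settings(2L),
                         ncs = sc$ncs)
  m <- mean(fit$draws[, "beta0"])
  s <- sd(fit$draws[, "beta0"])
  expect_lt(abs(m - sc$traj_params$beta[1]), 2 * s + 0.05)
})

test_that("draws are bit-for-bit reproducible under a fixed seed", {
  ds <- sim_fixture()
  st <- assoc_structure("current_value")
  f1 <- fit_joint_model(ds, st, settings = short_settings(5L))
  f2 <- fit_joint_model(ds, st, settings = short_settings(5L))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$ll_draws, f2$ll_draws)
  f3 <- fit_joint_model(ds, st, settings = short_settings(6L))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("posterior summaries follow the HR reporting convention", {
  d <- matrix(log(0.79), 100, 1, dimnames = list(NULL, "gamma_arm"))
  ps <- posterior_summary(d)
  expect_equal(ps["gamma_arm", "ratio"], 0.79)
  expect_equal(ps["gamma_arm", "ratio_lo"], 0.79)
  # symmetric draws around zero bracket HR = 1
  set.seed(2)
  z <- rnorm(4000, 0, 0.3)
  d2 <- cbind(alpha1 = c(z, -z))
  ps2 <- posterior_summary(d2)
  expect_lt(ps2["alpha1", "ratio_lo"], 1)
  expect_gt(ps2["alpha1", "ratio_hi"], 1)
  # quantiles agree with a sorted-array oracle
  set.seed(3)
  x <- rnorm(1e4)
  ps3 <- posterior_summary(cbind(theta = x))
  xs <- sort(x)
  q <- function(p) { # type-7 quantile, as used by stats::quantile
    h <- (length(xs) - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[lo + 1] - xs[lo])
  }
  expect_equal(ps3["theta", "q2.5"], q(0.025), tolerance = 1e-12)
  expect_equal(ps3["theta", "q97.5"], q(0.975), tolerance = 1e-12)
})

test_that("diagnostics: identical chains give R-hat 1, shifted chains are flagged, iid ESS is right", {
  set.seed(1)
  v <- rnorm(100)
  x <- rep(c(v, v), 2) # two byte-identical chains whose split halves match
  d <- diagnostics(cbind(theta = x), chain_id = rep(1:2, each = 200))
  expect_equal(d$rhat, 1, tolerance = 1e-12)
  expect_false(d$flagged)
  set.seed(4)
  iid <- matrix(rnorm(4000), ncol = 1, dimnames = list(NULL, "z"))
  d2 <- diagnostics(iid, chain_id = rep(1:2, each = 2000))
  expect_lt(abs(d2$ess - 4000) / 4000, 0.2)
  shifted <- cbind(w = c(rnorm(500), rnorm(500) + 5))
  d3 <- diagnostics(shifted, chain_id = rep(1:2, each = 500))
  expect_gt(d3$rhat, 1.1)
  expect_true(d3$flagged)
  expect_warning(diagnostics(cbind(a = rnorm(2)), chain_id = c(1L, 1L)),
                 "single short chain")
})

test_that("acceptance-rate pathologies raise a warning", {
  # near-zero follow-up and no events: the survival likelihood is flat, so
  # with frozen (unadapted) small proposal scales the (gamma, alpha) block
  # accepts essentially every proposal
  long <- data.frame(subject_id = 1:6, time = 0,
                     y = c(11, 12, 13, 10, 11.5, 12.5))
  long <- rbind(long, transform(long, time = 1e-6, y = y + 0.1),
                transform(long, time = 2e-6, y = y - 0.1))
  surv <- data.frame(subject_id = 1:6, time = 1e-5, event = 0L,
                     arm = rep(0:1, 3), age = 30, gender = 0L)
  ds <- trial_dataset(long, surv, meta = list(t_max = 1e-5))
  st <- assoc_structure("current_value")
  s <- mcmc_settings(n_chains = 1L, n_adapt = 0L, n_burnin = 20L,
                     n_iter = 200L, seed = 3L)
  expect_warning(fit_joint_model(ds, st, settings = s), "acceptance rate")
})
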