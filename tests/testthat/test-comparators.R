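test_that("Kaplan-Meier: no events, hand-checkable steps, monotone, survfit cross-check", {
  s0 <- data.frame(time = c(3, 5, 9), event = 0L)
  km0 <- km_estimator(s0)
  expect_equal(nrow(km0$all), 0L) # no event times, curve stays at 1
  s1 <- data.frame(time = c(1, 2, 3), event = c(1L, 1L, 0L))
  km1 <- km_estimator(s1)
  expect_equal(km1$all$surv, c(2 / 3, 1 / 3))
  ds <- sim_fixture()$survival
  km <- km_estimator(ds, ds$arm)
  for (g in names(km)) expect_true(all(diff(km[[g]]$surv) <= 0))
  expect_error(km_estimator(ds[0, ]), "empty")
  skip_if_not_installed("survival")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = ds)
  mine <- km_estimator(ds)$all
  idx <- match(mine$time, sf$time)
  expect_equal(mine$surv, sf$surv[idx], tolerance = 1e-12)
  expect_equal(mine$se, sf$std.err[idx] * sf$surv[idx], tolerance = 1e-8)
})

test_that("log-rank: null under label-duplication, hand oracle, swap invariance", {
  s <- data.frame(time = c(1, 2, 3, 4, 5, 6), event = c(1, 1, 0, 1, 1, 0))
  dup <- rbind(s, s)
  lr0 <- logrank_test(dup, rep(c("a", "b"), each = 6))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  # hand computation for a 6-subject toy
  g <- c("a", "a", "a", "b", "b", "b")
  lr <- logrank_test(s, g)
  # event times 1,2,4,5; risk sets 6,5,3,2; group-a members at risk 3,2,0,0
  O <- 2 # observed events in group a (times 1 and 2)
  E <- 3 / 6 + 2 / 5 + 0 / 3 + 0 / 2
  V <- (3 / 6) * (1 - 3 / 6) + (2 / 5) * (1 - 2 / 5) + 0 + 0
  expect_equal(lr$statistic, (O - E)^2 / V, tolerance = 1e-10)
  expect_equal(lr$statistic,
               logrank_test(s, ifelse(g == "a", "b", "a"))$statistic,
               tolerance = 1e-12)
  expect_error(logrank_test(s, rep("a", 6)), "two groups")
  skip_if_not_installed("survival")
  ds <- sim_fixture()$survival
  mine <- logrank_test(ds, ds$arm)
  ref <- survival::survdiff(survival::Surv(time, event) ~ arm, data = ds)
  expect_equal(mine$statistic, ref$chisq, tolerance = 1e-8)
})

test_that("person-years rates: closed forms and exact Poisson interval", {
  # 10 events over 100 person-years = 1200 person-months
  s <- data.frame(time = rep(120, 10), event = 1L)
  r <- py_rates(s)
  expect_equal(r$rate, 10)
  expect_equal(r$person_years, 100)
  # toy: 3 events over 26.1 person-years
  s2 <- data.frame(time = c(100, 113.2, 100), event = 1L)
  r2 <- py_rates(s2)
  expect_equal(r2$person_years, 313.2 / 12)
  expect_equal(r2$rate, 3 / (313.2 / 12) * 100)
  expect_equal(r2$lo, qchisq(0.025, 6) / 2 / (313.2 / 12) * 100)
  expect_equal(r2$hi, qchisq(0.975, 8) / 2 / (313.2 / 12) * 100)
  # zero events: rate 0 with a positive upper bound
  s3 <- data.frame(time = c(60, 60), event = 0L)
  r3 <- py_rates(s3)
  expect_equal(r3$rate, 0)
  expect_equal(r3$lo, 0)
  expect_gt(r3$hi, 0)
  expect_error(py_rates(data.frame(time = 0, event = 0L)), "zero follow-up")
})

test_that("counting-process construction carries the last observation forward", {
  long <- data.frame(subject_id = c(1L, 1L, 1L, 2L),
                     time = c(0, 2, 6, 0), y = c(10, 11, 12, 9))
  surv <- data.frame(subject_id = 1:2, time = c(10, 4), event = c(1L, 0L),
                     arm = 0L, age = 30, gender = 0L)
  ds <- trial_dataset(long, surv)
  cp <- build_counting_process(ds)
  s1 <- cp[cp$subject_id == 1L, ]
  expect_equal(s1$start, c(0, 2, 6))
  expect_equal(s1$stop, c(2, 6, 10))
  expect_equal(s1$locf_sqrt_cd4, c(10, 11, 12))
  expect_equal(s1$event, c(0L, 0L, 1L))
  s2 <- cp[cp$subject_id == 2L, ]
  expect_equal(nrow(s2), 1L)
  expect_equal(s2$locf_sqrt_cd4, 9)
  expect_equal(s2$event, 0L)
  # row count: one interval per measurement strictly before T
  ds2 <- sim_fixture()
  cp2 <- build_counting_process(ds2)
  expected <- sum(ds2$longitudinal$time <
                    ds2$survival$time[match(ds2$longitudinal$subject_id,
                                            ds2$survival$subject_id)])
  expect_equal(nrow(cp2), expected)
})

test_that("KM from the counting-process representation equals KM from the plain table", {
  ds <- sim_fixture()
  cp <- build_counting_process(ds)
  last <- cp[!duplicated(cp$subject_id, fromLast = TRUE), ]
  km_cp <- km_estimator(data.frame(time = last$stop, event = last$event))
  km_pl <- km_estimator(ds$survival)
  expect_equal(km_cp$all$surv, km_pl$all$surv)
})

test_that("tv-Cox: grid-search oracle, constant covariate, stationarity, coxph cross-check", {
  long <- data.frame(subject_id = 1:4, time = 0, y = c(8, 12, 9, 14))
  surv <- data.frame(subject_id = 1:4, time = c(2, 4, 6, 8),
                     event = c(1L, 1L, 1L, 0L), arm = c(0L, 1L, 0L, 1L),
                     age = 30, gender = 0L)
  ds <- trial_dataset(long, surv)
  cp <- build_counting_process(ds)
  fit <- fit_tv_cox(cp, covariates = "arm")
  # brute-force grid over the single coefficient
  grid <- seq(-5, 5, by = 1e-4)
  pl <- vapply(grid, function(bb)
    jmassoc:::.coxcp_loglik(bb, cp, matrix(cp$arm, ncol = 1))$ll, numeric(1))
  expect_lt(abs(fit$coef[["arm"]] - grid[which.max(pl)]), 1e-3)
  expect_lt(max(abs(fit$gradient)), 1e-8)
  # constant covariate: coefficient 0, HR 1
  fit_const <- fit_tv_cox(cp, covariates = c("age", "arm"))
  expect_equal(fit_const$coef[["age"]], 0)
  expect_equal(fit_const$hr[["age"]], 1)
  skip_if_not_installed("survival")
  ds2 <- sim_fixture()
  cp2 <- build_counting_process(ds2)
  mine <- fit_tv_cox(cp2)
  ref <- survival::coxph(
    survival::Surv(start, stop, event) ~ locf_sqrt_cd4 + arm + age + gender,
    data = cp2, ties = "breslow")
  expect_equal(unname(mine$coef), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(mine$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-5)
})

test_that("tv-Cox on never-updated CD4 equals the baseline-CD4 Cox model", {
  ds <- sim_fixture()
  base_only <- ds$longitudinal[ds$longitudinal$time == 0, ]
  ds0 <- trial_dataset(base_only, ds$survival, meta = ds$meta)
  cp0 <- build_counting_process(ds0)
  mine <- fit_tv_cox(cp0)
  skip_if_not_installed("survival")
  df <- ds$survival
  df$y0 <- base_only$y[match(df$subject_id, base_only$subject_id)]
  ref <- survival::coxph(survival::Surv(time, event) ~ y0 + arm + age +
                           gender, data = df, ties = "breslow")
  expect_equal(unname(mine$coef), unname(coef(ref)), tolerance = 1e-6)
})

test_that("log-rank equals the Cox score test at beta = 0 on a fixture", {
  ds <- sim_fixture()$survival
  lr <- logrank_test(ds, ds$arm)
  skip_if_not_installed("survival")
  ref <- survival::coxph(survival::Surv(time, event) ~ arm, data = ds,
                         ties = "breslow")
  expect_equal(lr$statistic, ref$score, tolerance = 1e-8)
})
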