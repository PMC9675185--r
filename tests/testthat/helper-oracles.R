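# Independent oracles used across the suite.  These deliberately avoid the
# package's own spline construction.

# Truncated-power natural cubic spline basis over all knots (boundary +
# interior): columns {1, t, constrained (t - k)+^3 directions}.  Any natural
# cubic spline on these knots lies in this column space.
tp_natural_basis <- function(t, all_knots) {
  K <- length(all_knots)
  cubes <- sapply(all_knots, function(k) pmax(t - k, 0)^3)
  # linear-beyond-last-knot constraints: sum c = 0, sum c * knot = 0
  C <- rbind(rep(1, K), all_knots)
  N <- qr.Q(qr(t(C)), complete = TRUE)[, seq_len(K - 2L) + 2L, drop = FALSE]
  cbind(1, t, cubes %*% N)
}

# residual of projecting f(t_grid) onto the truncated-power space
tp_projection_residual <- function(f_vals, t_grid, all_knots) {
  X <- tp_natural_basis(t_grid, all_knots)
  max(abs(stats::lm.fit(X, f_vals)$residuals))
}

# naive recursive Cox-de-Boor B-spline evaluation, one basis function
naive_bspline <- function(x, knots, j, ord) {
  if (ord == 1L)
    return(as.numeric(knots[j] <= x & x < knots[j + 1L]))
  d1 <- knots[j + ord - 1L] - knots[j]
  d2 <- knots[j + ord] - knots[j + 1L]
  t1 <- if (d1 > 0) (x - knots[j]) / d1 * naive_bspline(x, knots, j, ord - 1L) else 0
  t2 <- if (d2 > 0) (knots[j + ord] - x) / d2 *
      naive_bspline(x, knots, j + 1L, ord - 1L) else 0
  t1 + t2
}

# small deterministic two-subject dataset used by likelihood hand-checks
tiny_dataset <- function() {
  long <- data.frame(
    subject_id = c(1L, 1L, 1L, 2L, 2L),
    time = c(0, 2, 6, 0, 2),
    y = c(11.5, 12.4, 13.1, 9.8, 10.9))
  surv <- data.frame(
    subject_id = c(1L, 2L), time = c(8, 4), event = c(1L, 0L),
    arm = c(1L, 0L), age = c(30, 40), gender = c(1L, 0L))
  trial_dataset(long, surv, meta = list(t_max = 10))
}

# moderate simulated dataset reused by several expensive tests
sim_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_trial(trial_design(n_subjects = 60, seed = 424L),
                               default_scenario("current_value"))
    cache
  }
})

fixture_specs <- function(dataset) {
  list(ncs = default_ncs_spec(dataset), bspec = default_bspline_spec(dataset))
}
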