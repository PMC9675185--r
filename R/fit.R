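#' Prior specification
#'
#' Defaults: regression-type coefficients (fixed effects, log hazard ratios,
#' association coefficients, baseline spline coefficients) are independent
#' Normal(0, 100) (variance 100); the residual variance is
#' Inverse-Gamma(0.01, 0.01); the random-effects covariance is decomposed
#' into scales with Half-Cauchy(2.5) priors and a correlation matrix uniform
#' over valid correlation matrices; the log weight-kernel scale is
#' Normal(log(t_max / 4), 1).
#'
#' @param coef_sd prior SD of all regression-type coefficients.
#' @param sigma2_shape,sigma2_rate Inverse-Gamma hyperparameters for the
#'   residual variance.
#' @param ranef_scale Half-Cauchy scale for the random-effect SDs.
#' @param logsw_mean,logsw_sd normal prior for `log(sigma_w)`; `NULL` mean
#'   defaults to `log(t_max / 4)` at fit time.
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(coef_sd = 10, sigma2_shape = 0.01,
                       sigma2_rate = 0.01, ranef_scale = 2.5,
                       logsw_mean = NULL, logsw_sd = 1) {
  stopifnot(coef_sd > 0, sigma2_shape > 0, sigma2_rate > 0, ranef_scale > 0,
            logsw_sd > 0)
  structure(list(coef_sd = coef_sd, sigma2_shape = sigma2_shape,
                 sigma2_rate = sigma2_rate, ranef_scale = ranef_scale,
                 logsw_mean = logsw_mean, logsw_sd = logsw_sd),
            class = "prior_spec")
}

#' MCMC settings
#'
#' @param n_chains number of chains.
#' @param n_adapt adaptation iterations (proposal scales tuned by
#'   Robbins-Monro towards 0.234 for blocks and 0.44 for scalars, then
#'   frozen).
#' @param n_burnin post-adaptation burn-in iterations (discarded).
#' @param n_iter kept iterations per chain.
#' @param thin thinning interval.
#' @param seed integer RNG seed (chain c uses `seed + c - 1`).
#' @param target_accept length-2: target acceptance for block and scalar
#'   updates.
#' @param store_ranef keep the random-effect draws (running means are always
#'   tracked).
#' @return object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 3L, n_adapt = 1000L, n_burnin = 1000L,
                          n_iter = 2000L, thin = 1L, seed = 1L,
                          target_accept = c(block = 0.234, scalar = 0.44),
                          store_ranef = FALSE) {
  stopifnot(n_chains >= 1, n_adapt >= 0, n_burnin >= 0, n_iter >= 1,
            thin >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_adapt = as.integer(n_adapt),
                 n_burnin = as.integer(n_burnin),
                 n_iter = as.integer(n_iter), thin = as.integer(thin),
                 seed = as.integer(seed), target_accept = target_accept,
                 store_ranef = isTRUE(store_ranef)),
            class = "mcmc_settings")
}

#' Initial parameter state
#'
#' Least-squares pass over the longitudinal data for the fixed effects,
#' per-subject curve fits for the random effects and their covariance, a
#' baseline-covariates-only exponential (Poisson with log-time offset) fit
#' for the gamma coefficients, a crude piecewise-constant hazard projected
#' onto the baseline spline for k, and alpha = 0. With no events at all,
#' gamma and k fall back to the prior means (zero, with a small-hazard
#' intercept).
#'
#' @param dataset a [trial_dataset()].
#' @param structure an [assoc_structure()].
#' @param ncs,bspec basis specifications.
#' @return list of initial values.
#' @export
init_joint_model <- function(dataset, structure, ncs, bspec) {
  long <- dataset$longitudinal
  s <- dataset$survival
  if (length(unique(long$time)) < 3L)
    stop("fewer than 3 distinct measurement times: spline unidentifiable")
  X <- cbind(1, ncs_basis(long$time, ncs))
  p <- ncol(X)
  fit <- stats::lm.fit(X, long$y)
  beta <- unname(fit$coefficients)
  beta[!is.finite(beta)] <- 0
  # per-subject residual curves -> crude random effects
  res <- long$y - drop(X %*% beta)
  ids <- unique(long$subject_id)
  bhat <- matrix(0, length(ids), p)
  for (j in seq_along(ids)) {
    rows <- which(long$subject_id == ids[j])
    Xi <- X[rows, , drop = FALSE]
    # ridge-stabilised least squares (few observations per subject)
    bhat[j, ] <- drop(solve(crossprod(Xi) + diag(0.5, p),
                            crossprod(Xi, res[rows])))
  }
  D <- stats::cov(bhat)
  if (nrow(bhat) < 10L || inherits(try(chol(D), silent = TRUE), "try-error"))
    D <- diag(c(2, 1, 1)[seq_len(p)]^2)
  D <- D + diag(0.05, p)
  idx <- match(long$subject_id, s$subject_id)
  mu <- drop(X %*% beta) + rowSums(X * bhat[match(long$subject_id, ids), ])
  sigma2 <- max(stats::var(long$y - mu), 0.05)

  n_events <- sum(s$event)
  if (n_events == 0L) {
    gamma <- c(0, 0, 0)
    k <- c(log(0.01), rep(0, ncol(.baseline_design(0, bspec)) - 1L))
  } else {
    pt <- pmax(s$time, 1e-6)
    gfit <- suppressWarnings(
      stats::glm(s$event ~ s$arm + s$age + s$gender + offset(log(pt)),
                 family = stats::poisson()))
    gamma <- unname(gfit$coefficients[2:4])
    gamma[!is.finite(gamma)] <- 0
    # piecewise-constant hazard, projected onto the baseline spline
    edges <- unique(c(0, 6, 12, 24, 36, 48, max(s$time)))
    edges <- edges[edges <= max(s$time)]
    if (edges[length(edges)] < max(s$time)) edges <- c(edges, max(s$time))
    mids <- rates <- numeric(0)
    for (j in seq_len(length(edges) - 1L)) {
      lo <- edges[j]; hi <- edges[j + 1L]
      py <- sum(pmax(pmin(s$time, hi) - lo, 0))
      ev <- sum(s$event == 1 & s$time > lo & s$time <= hi)
      if (py > 0) {
        mids <- c(mids, (lo + hi) / 2)
        rates <- c(rates, max(ev, 0.5) / py)
      }
    }
    Xb <- .baseline_design(mids, bspec)
    k <- drop(solve(crossprod(Xb) + diag(0.1, ncol(Xb)),
                    crossprod(Xb, log(rates))))
  }
  out <- list(beta = beta, b = matrix(0, nrow(s), p), sigma2_eps = sigma2,
              D = D, gamma = gamma, alpha1 = 0,
              alpha2 = if (structure$tag == "slopes") 0, k = k)
  if (structure$tag == "weighted_cumulative")
    out$sigma_w <- structure$weight$t_max / 4
  out
}

# --- internal sampler helpers -----------------------------------------------

.cor_from_offdiag <- function(r) {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- r[1]
  R[1, 3] <- R[3, 1] <- r[2]
  R[2, 3] <- R[3, 2] <- r[3]
  R
}

.is_pd <- function(R) !inherits(try(chol(R), silent = TRUE), "try-error")

.lp_coef <- function(x, sd) sum(stats::dnorm(x, 0, sd, log = TRUE))

.lp_halfcauchy <- function(s, scale) {
  if (any(s <= 0)) return(-Inf)
  sum(stats::dcauchy(s, 0, scale, log = TRUE))
}

# Robbins-Monro log-scale adaptation step
.adapt_scale <- function(scale, acc, target, it) {
  scale * exp(min(0.25, it^-0.6) * (acc - target))
}

# Adaptive-Metropolis block state: a Robbins-Monro scalar step size times a
# Cholesky preconditioner learned from the chain's own history (Welford
# running covariance, refreshed periodically during adaptation, frozen
# afterwards).  Crucial for the correlated baseline-spline coefficients.
.block_new <- function(d, diag_pre = rep(1, d), scale = 0.1) {
  list(d = d, scale = scale, L = diag(diag_pre, d),
       n = 0L, mean = rep(0, d), M2 = matrix(0, d, d))
}

.block_propose <- function(bl, cur) {
  cur + bl$scale * drop(stats::rnorm(bl$d) %*% bl$L)
}

.block_learn <- function(bl, x, acc, target, it, refresh = 25L) {
  bl$scale <- .adapt_scale(bl$scale, acc, target, it)
  bl$n <- bl$n + 1L
  delta <- x - bl$mean
  bl$mean <- bl$mean + delta / bl$n
  bl$M2 <- bl$M2 + tcrossprod(delta, x - bl$mean)
  if (bl$n > 10L * bl$d && bl$n %% refresh == 0L) {
    S <- bl$M2 / (bl$n - 1L)
    S <- S + diag(1e-10 + 1e-4 * mean(diag(S)), bl$d)
    ch <- try(chol(S), silent = TRUE)
    if (!inherits(ch, "try-error")) {
      if (bl$n == 0L || is.null(bl$learned)) # first adoption: rescale once
        bl$scale <- 2.38 / sqrt(bl$d)
      bl$L <- ch
      bl$learned <- TRUE
    }
  }
  bl
}

#' Fit the joint model by MCMC
#'
#' Adaptive random-walk Metropolis-within-Gibbs: blocked updates for the
#' fixed effects, the (gamma, alpha) survival coefficients, the baseline
#' spline coefficients and the random-effect correlations; subject-wise
#' (vectorised) updates for the random effects; Gibbs for the residual
#' variance; scalar log-walks for the random-effect scales and the weight
#' kernel scale. Proposal scales adapt during `n_adapt` iterations and are
#' then frozen.
#'
#' @param dataset a [trial_dataset()].
#' @param structure an [assoc_structure()]; for `weighted_cumulative` the
#'   kernel scale is estimated (log-normal prior) starting from the
#'   structure's `weight_spec`.
#' @param priors a [prior_spec()].
#' @param settings an [mcmc_settings()].
#' @param ncs trajectory spline; default: boundary at the observed
#'   measurement-time range, one interior knot at the median pooled
#'   measurement time.
#' @param bspec baseline-hazard spline; default: cubic, 5 interior knots at
#'   equally spaced percentiles of the observed event times, support
#'   `[0, t_max]`.
#' @param init initial state, default [init_joint_model()].
#' @param likelihood `"joint"` (default), `"longitudinal"` (survival part
#'   excluded; used for conjugate cross-checks) or `"none"` (prior-only
#'   sampling, which validates the sampler kernel).
#' @param fix named list of components to hold fixed (any of `beta`, `b`,
#'   `sigma2_eps`, `D`, `gamma`, `alpha1`, `alpha2`, `k`, `sigma_w`).
#' @return object of class `jm_fit`.
#' @export
fit_joint_model <- function(dataset, structure, priors = prior_spec(),
                            settings = mcmc_settings(), ncs = NULL,
                            bspec = NULL, init = NULL,
                            likelihood = c("joint", "longitudinal", "none"),
                            fix = list()) {
  stopifnot(inherits(dataset, "trial_dataset"),
            inherits(structure, "assoc_structure"))
  likelihood <- match.arg(likelihood)
  s <- dataset$survival
  n <- nrow(s)
  t_max <- dataset$meta$t_max

  if (is.null(ncs)) ncs <- default_ncs_spec(dataset)
  if (is.null(bspec)) bspec <- default_bspline_spec(dataset)
  if (is.null(init)) init <- init_joint_model(dataset, structure, ncs, bspec)

  use_long <- likelihood %in% c("joint", "longitudinal")
  use_surv <- likelihood == "joint"
  # with likelihood = "none" the survival-side parameters are still sampled
  # (from their priors), which is what the kernel-validation mode checks
  samp_surv <- likelihood %in% c("joint", "none")
  lc <- if (use_long) build_long_cache(dataset, ncs)
  sc <- if (use_surv) build_surv_cache(dataset, structure, bspec, ncs)
  weighted <- structure$tag == "weighted_cumulative"
  slopes <- structure$tag == "slopes"
  nk <- length(init$k)
  p <- length(init$beta)
  if (is.null(priors$logsw_mean)) priors$logsw_mean <- log(t_max / 4)

  is_fixed <- function(nm) nm %in% names(fix)
  for (nm in names(fix)) init[[nm]] <- fix[[nm]]

  # automatic proposal preconditioning for alpha: scale of the association
  # covariate at the event times under the initial trajectory
  assoc_sd <- 1
  slope_sd <- 1
  if (use_surv && length(sc$ev_idx) >= 2L) {
    cf0 <- sweep(init$b, 2L, init$beta, "+")
    at0 <- .assoc_raw(sc, cf0, init$sigma_w)
    assoc_sd <- max(stats::sd(at0$f_ev), 0.1, na.rm = TRUE)
    if (slopes) slope_sd <- max(stats::sd(at0$fd_ev), 0.1, na.rm = TRUE)
  }

  par_names <- c(paste0("beta", seq_len(p) - 1L), "sigma2_eps",
                 paste0("D_sd", seq_len(p)),
                 c("D_cor12", "D_cor13", "D_cor23"),
                 "gamma_arm", "gamma_age", "gamma_gender", "alpha1",
                 if (slopes) "alpha2", paste0("k", seq_len(nk) - 1L),
                 if (weighted) "log_sigma_w")
  keep_total <- settings$n_chains * (settings$n_iter %/% settings$thin)
  draws <- matrix(NA_real_, keep_total, length(par_names),
                  dimnames = list(NULL, par_names))
  chain_id <- integer(keep_total)
  ll_draws <- numeric(keep_total)
  ll_subj <- matrix(NA_real_, keep_total, n)
  b_draws <- if (settings$store_ranef)
    matrix(NA_real_, keep_total, n * p) else NULL
  b_mean <- matrix(0, n, p)
  row_out <- 0L
  acc_log <- list()

  for (chain in seq_len(settings$n_chains)) {
    set.seed(settings$seed + chain - 1L)
    st <- init
    st$sds <- sqrt(diag(st$D))
    R0 <- stats::cov2cor(st$D)
    st$r <- c(R0[1, 2], R0[1, 3], R0[2, 3])
    if (weighted && is.null(st$sigma_w)) st$sigma_w <- t_max / 4

    coefs <- function() sweep(st$b, 2L, st$beta, "+")
    raw_cur <- if (use_surv) .assoc_raw(sc, coefs(), st$sigma_w)
    long_v <- if (use_long) long_loglik_cached(lc, coefs(), st$sigma2_eps)
      else numeric(n)
    surv_v <- if (use_surv)
      surv_loglik_cached(sc, st$k, st$gamma, st$alpha1, st$alpha2, coefs(),
                         st$sigma_w, raw = raw_cur) else numeric(n)
    bpri_v <- .dmvnorm_log(st$b, st$D)
    if (!all(is.finite(c(long_v, surv_v, bpri_v))))
      stop("non-finite posterior at initialization")

    scales <- list(sds = rep(0.3, p), lsw = 0.3)
    ga_pre <- c(0.5, 0.02, 0.5, 0.5 / assoc_sd, if (slopes) 0.5 / slope_sd)
    blk <- list(beta = .block_new(p, rep(0.2, p)),
                ga = .block_new(length(ga_pre), ga_pre, scale = 0.3),
                k = .block_new(nk, rep(1, nk), scale = 0.15),
                r = .block_new(3L, rep(1, 3L), scale = 0.15))
    acc <- list(beta = 0, ga = 0, k = 0, r = 0, lsw = 0, b = 0)
    ntot <- settings$n_adapt + settings$n_burnin +
      settings$n_iter
    n_since <- 0L

    for (it in seq_len(ntot)) {
      adapting <- it <= settings$n_adapt
      n_since <- n_since + 1L

      ## fixed effects block
      if (!is_fixed("beta")) {
        prop <- .block_propose(blk$beta, st$beta)
        cf <- sweep(st$b, 2L, prop, "+")
        lv <- if (use_long) long_loglik_cached(lc, cf, st$sigma2_eps)
          else numeric(n)
        raw_p <- if (use_surv)
          .assoc_raw(sc, cf, st$sigma_w, G = raw_cur$G)
        sv <- if (use_surv)
          surv_loglik_cached(sc, st$k, st$gamma, st$alpha1, st$alpha2, cf,
                             st$sigma_w, raw = raw_p) else numeric(n)
        lr <- sum(lv) - sum(long_v) + sum(sv) - sum(surv_v) +
          .lp_coef(prop, priors$coef_sd) - .lp_coef(st$beta, priors$coef_sd)
        a <- is.finite(lr) && log(stats::runif(1)) < lr
        if (a) {
          st$beta <- prop; long_v <- lv; surv_v <- sv
          if (use_surv) raw_cur <- raw_p
        }
        acc$beta <- acc$beta + a
        if (adapting)
          blk$beta <- .block_learn(blk$beta, st$beta, as.numeric(a),
                                   settings$target_accept[["block"]], it)
      }

      ## random effects, all subjects in parallel: conjugate independence
      ## proposal, Metropolis-corrected by the survival likelihood ratio
      if (!is_fixed("b")) {
        Dinv <- chol2inv(chol(st$D))
        bprop <- propose_b_conjugate(if (use_long) lc, st$beta,
                                     st$sigma2_eps, Dinv, n, p)
        cf <- sweep(bprop, 2L, st$beta, "+")
        lv <- if (use_long) long_loglik_cached(lc, cf, st$sigma2_eps)
          else numeric(n)
        raw_p <- if (use_surv)
          .assoc_raw(sc, cf, st$sigma_w, G = raw_cur$G)
        sv <- if (use_surv)
          surv_loglik_cached(sc, st$k, st$gamma, st$alpha1, st$alpha2, cf,
                             st$sigma_w, raw = raw_p) else numeric(n)
        bp <- .dmvnorm_log(bprop, st$D)
        lr <- sv - surv_v # Gaussian target and proposal terms cancel
        a <- is.finite(lr) & log(stats::runif(n)) < lr
        if (any(a)) {
          st$b[a, ] <- bprop[a, ]
          long_v[a] <- lv[a]; surv_v[a] <- sv[a]; bpri_v[a] <- bp[a]
          if (use_surv) raw_cur <- .raw_splice(sc, raw_cur, raw_p, a)
        }
        acc$b <- acc$b + mean(a)
      }

      ## centering sweep: a translation (beta + delta, b_i - delta) leaves
      ## every likelihood term unchanged (the coefficient rows beta + b_i
      ## are invariant), so delta has a Gaussian full conditional from the
      ## random-effects density and the beta prior; this Gibbs move removes
      ## the beta / mean(b) ridge that a random walk crawls along
      if (!is_fixed("beta") && !is_fixed("b")) {
        Dinv <- chol2inv(chol(st$D))
        P <- n * Dinv + diag(p) / priors$coef_sd^2
        U <- chol(P)
        mdelta <- backsolve(U, forwardsolve(
          t(U), Dinv %*% colSums(st$b) - st$beta / priors$coef_sd^2))
        delta <- drop(mdelta + backsolve(U, stats::rnorm(p)))
        st$beta <- st$beta + delta
        st$b <- sweep(st$b, 2L, delta, "-")
        bpri_v <- .dmvnorm_log(st$b, st$D)
      }

      ## residual variance: conjugate Gibbs
      if (!is_fixed("sigma2_eps") && use_long) {
        mu <- rowSums(lc$X * coefs()[lc$idx, , drop = FALSE])
        ss <- sum((lc$y - mu)^2)
        st$sigma2_eps <- 1 / stats::rgamma(
          1L, priors$sigma2_shape + length(lc$y) / 2,
          priors$sigma2_rate + ss / 2)
        long_v <- long_loglik_cached(lc, coefs(), st$sigma2_eps)
      } else if (!is_fixed("sigma2_eps")) {
        st$sigma2_eps <- 1 / stats::rgamma(1L, priors$sigma2_shape,
                                           priors$sigma2_rate)
      }

      ## random-effects covariance: scales then correlations
      if (!is_fixed("D")) {
        for (j in seq_len(p)) {
          prop <- st$sds
          prop[j] <- prop[j] * exp(scales$sds[j] * stats::rnorm(1))
          Dp <- diag(prop) %*% .cor_from_offdiag(st$r) %*% diag(prop)
          bp <- .dmvnorm_log(st$b, Dp)
          lr <- sum(bp) - sum(bpri_v) +
            .lp_halfcauchy(prop[j], priors$ranef_scale) -
            .lp_halfcauchy(st$sds[j], priors$ranef_scale) +
            log(prop[j]) - log(st$sds[j]) # log-scale walk Jacobian
          a <- is.finite(lr) && log(stats::runif(1)) < lr
          if (a) { st$sds <- prop; st$D <- Dp; bpri_v <- bp }
          if (adapting)
            scales$sds[j] <- .adapt_scale(scales$sds[j], as.numeric(a),
                                          settings$target_accept[["scalar"]],
                                          it)
        }
        rp <- .block_propose(blk$r, st$r)
        Rp <- .cor_from_offdiag(rp)
        if (all(abs(rp) < 1) && .is_pd(Rp)) {
          Dp <- diag(st$sds) %*% Rp %*% diag(st$sds)
          bp <- .dmvnorm_log(st$b, Dp)
          lr <- sum(bp) - sum(bpri_v)
          a <- is.finite(lr) && log(stats::runif(1)) < lr
          if (a) { st$r <- rp; st$D <- Dp; bpri_v <- bp }
        } else a <- FALSE
        acc$r <- acc$r + a
        if (adapting)
          blk$r <- .block_learn(blk$r, st$r, as.numeric(a),
                                settings$target_accept[["block"]], it)
      }

      ## survival coefficients (gamma, alpha) block
      if (samp_surv && !is_fixed("gamma")) {
        cur <- c(st$gamma, st$alpha1, if (slopes) st$alpha2)
        prop <- .block_propose(blk$ga, cur)
        sv <- if (use_surv)
          surv_loglik_cached(sc, st$k, prop[1:3], prop[4],
                             if (slopes) prop[5], coefs(), st$sigma_w,
                             raw = raw_cur) else numeric(n)
        lr <- sum(sv) - sum(surv_v) +
          .lp_coef(prop, priors$coef_sd) - .lp_coef(cur, priors$coef_sd)
        a <- is.finite(lr) && log(stats::runif(1)) < lr
        if (a) {
          st$gamma <- prop[1:3]; st$alpha1 <- prop[4]
          if (slopes) st$alpha2 <- prop[5]
          surv_v <- sv
        }
        acc$ga <- acc$ga + a
        if (adapting)
          blk$ga <- .block_learn(blk$ga,
                                 c(st$gamma, st$alpha1,
                                   if (slopes) st$alpha2), as.numeric(a),
                                 settings$target_accept[["block"]], it)
      }

      ## baseline spline coefficients block
      if (samp_surv && !is_fixed("k")) {
        prop <- .block_propose(blk$k, st$k)
        sv <- if (use_surv)
          surv_loglik_cached(sc, prop, st$gamma, st$alpha1, st$alpha2,
                             coefs(), st$sigma_w, raw = raw_cur)
          else numeric(n)
        lr <- sum(sv) - sum(surv_v) +
          .lp_coef(prop, priors$coef_sd) - .lp_coef(st$k, priors$coef_sd)
        a <- is.finite(lr) && log(stats::runif(1)) < lr
        if (a) { st$k <- prop; surv_v <- sv }
        acc$k <- acc$k + a
        if (adapting)
          blk$k <- .block_learn(blk$k, st$k, as.numeric(a),
                                settings$target_accept[["block"]], it)
      }

      ## weight-kernel scale (log walk); updated every 4th sweep because a
      ## sigma_w move re-aggregates the whole inner quadrature, and the
      ## kernel scale is the most weakly identified parameter in the model
      if (samp_surv && weighted && !is_fixed("sigma_w") && it %% 4L == 1L) {
        lsw <- log(st$sigma_w) + scales$lsw * stats::rnorm(1)
        raw_p <- if (use_surv) .assoc_raw(sc, coefs(), exp(lsw))
        sv <- if (use_surv)
          surv_loglik_cached(sc, st$k, st$gamma, st$alpha1, st$alpha2,
                             coefs(), exp(lsw), raw = raw_p)
          else numeric(n)
        lr <- sum(sv) - sum(surv_v) +
          stats::dnorm(lsw, priors$logsw_mean, priors$logsw_sd, log = TRUE) -
          stats::dnorm(log(st$sigma_w), priors$logsw_mean, priors$logsw_sd,
                       log = TRUE)
        a <- is.finite(lr) && log(stats::runif(1)) < lr
        if (a) { st$sigma_w <- exp(lsw); surv_v <- sv; raw_cur <- raw_p }
        acc$lsw <- acc$lsw + a
        if (adapting)
          scales$lsw <- .adapt_scale(scales$lsw, as.numeric(a),
                                     settings$target_accept[["scalar"]], it)
      }

      ## store
      post_burn <- it > settings$n_adapt + settings$n_burnin
      if (post_burn &&
          (it - settings$n_adapt - settings$n_burnin) %% settings$thin == 0) {
        row_out <- row_out + 1L
        draws[row_out, ] <- c(st$beta, st$sigma2_eps, st$sds, st$r,
                              st$gamma, st$alpha1, if (slopes) st$alpha2,
                              st$k, if (weighted) log(st$sigma_w))
        chain_id[row_out] <- chain
        ll_draws[row_out] <- sum(long_v) + sum(surv_v)
        ll_subj[row_out, ] <- long_v + surv_v
        b_mean <- b_mean + st$b
        if (settings$store_ranef) b_draws[row_out, ] <- as.vector(st$b)
      }
    }
    rate <- vapply(acc, function(x) x / ntot, numeric(1L))
    acc_log[[chain]] <- rate
    bad <- rate[c("beta", "ga", "k", "r")] < 0.05 |
      rate[c("beta", "ga", "k", "r")] > 0.95
    if (use_surv && any(bad, na.rm = TRUE))
      warning("acceptance rate outside [0.05, 0.95] for block(s): ",
              paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  }
  b_mean <- b_mean / row_out

  structure(list(
    draws = draws, chain_id = chain_id, ll_draws = ll_draws,
    ll_subj = ll_subj, b_mean = b_mean, b_draws = b_draws,
    structure = structure, ncs = ncs, bspec = bspec, priors = priors,
    settings = settings, init = init, likelihood = likelihood,
    acceptance = acc_log, dataset = dataset,
    dataset_fingerprint = .dataset_fingerprint(dataset),
    n_subjects = n
  ), class = "jm_fit")
}

#' Default spline specifications from the data
#'
#' Trajectory spline: boundary knots at the observed measurement-time range,
#' one interior knot at the median of the pooled measurement times. Baseline
#' spline: cubic, interior knots at equally spaced percentiles of the
#' observed event times (fewer knots if there are few distinct event times),
#' support `[0, t_max]`.
#'
#' @param dataset a [trial_dataset()].
#' @param n_interior number of interior knots for the baseline spline.
#' @return an [ncs_spec()] / [bspline_spec()].
#' @export
default_ncs_spec <- function(dataset) {
  tt <- dataset$longitudinal$time
  lo <- min(tt); hi <- max(tt)
  knot <- stats::median(tt)
  if (knot <= lo || knot >= hi) knot <- (lo + hi) / 2
  ncs_spec(c(lo, hi), knot)
}

#' @rdname default_ncs_spec
#' @export
default_bspline_spec <- function(dataset, n_interior = 5L) {
  t_max <- dataset$meta$t_max
  ev <- dataset$survival$time[dataset$survival$event == 1]
  if (length(ev) >= 2L) {
    qs <- stats::quantile(ev, probs = seq_len(n_interior) /
                            (n_interior + 1L), names = FALSE)
    qs <- unique(pmin(pmax(qs, t_max * 0.02), t_max * 0.98))
    if (length(qs) < length(unique(qs)) || anyDuplicated(qs))
      qs <- unique(qs)
    if (!length(qs)) qs <- t_max / 2
  } else {
    qs <- t_max * seq_len(n_interior) / (n_interior + 1L)
  }
  bspline_spec(c(0, t_max), sort(unique(qs)), degree = 3L)
}
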