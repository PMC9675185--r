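#' Deviance of a log-likelihood value
#'
#' `-2 * loglik`, with the additive constant fixed at zero (the likelihood
#' already carries its full normalising constants, and any constant cancels
#' in model comparison).
#'
#' @param loglik scalar log-likelihood.
#' @return deviance.
#' @export
deviance_value <- function(loglik) -2 * loglik

# parameters at the componentwise posterior mean (random effects included)
.theta_bar <- function(fit) {
  cm <- colMeans(fit$draws)
  p <- ncol(fit$b_mean)
  sds <- cm[paste0("D_sd", seq_len(p))]
  R <- .cor_from_offdiag(cm[c("D_cor12", "D_cor13", "D_cor23")])
  list(beta = unname(cm[paste0("beta", seq_len(p) - 1L)]),
       sigma2_eps = unname(cm[["sigma2_eps"]]),
       D = diag(sds) %*% R %*% diag(sds),
       gamma = unname(cm[c("gamma_arm", "gamma_age", "gamma_gender")]),
       alpha1 = unname(cm[["alpha1"]]),
       alpha2 = if ("alpha2" %in% names(cm)) unname(cm[["alpha2"]]),
       k = unname(cm[grep("^k\\d+$", names(cm))]),
       sigma_w = if ("log_sigma_w" %in% names(cm))
         exp(unname(cm[["log_sigma_w"]])),
       b = fit$b_mean)
}

# conditional (on b) data log-likelihood at a parameter state, via the
# cached fast path
.loglik_at <- function(fit, th) {
  coefs <- sweep(th$b, 2L, th$beta, "+")
  ll <- 0
  if (fit$likelihood %in% c("joint", "longitudinal")) {
    lc <- build_long_cache(fit$dataset, fit$ncs)
    ll <- ll + sum(long_loglik_cached(lc, coefs, th$sigma2_eps))
  }
  if (fit$likelihood == "joint") {
    scache <- build_surv_cache(fit$dataset, fit$structure, fit$bspec,
                               fit$ncs)
    ll <- ll + sum(surv_loglik_cached(scache, th$k, th$gamma, th$alpha1,
                                      th$alpha2, coefs, th$sigma_w))
  }
  ll
}

#' Effective number of parameters (pD)
#'
#' Mean posterior deviance minus the deviance at the componentwise posterior
#' mean of all parameters and random effects, using the per-draw
#' log-likelihoods stored during sampling plus one likelihood evaluation at
#' the posterior mean.
#'
#' @param fit a `jm_fit`.
#' @return list with `p_d`, `d_bar` (mean posterior deviance) and
#'   `d_at_mean`.
#' @export
p_d <- function(fit) {
  stopifnot(inherits(fit, "jm_fit"))
  if (!length(fit$ll_draws) || all(is.na(fit$ll_draws)))
    stop("fit carries no stored log-likelihood draws")
  d_bar <- mean(deviance_value(fit$ll_draws))
  d_at_mean <- deviance_value(.loglik_at(fit, .theta_bar(fit)))
  list(p_d = d_bar - d_at_mean, d_bar = d_bar, d_at_mean = d_at_mean)
}

#' Deviance information criterion
#'
#' `DIC = D(theta_bar) + 2 pD`, algebraically equal to the mean posterior
#' deviance plus pD; both identities are computed from the same pieces so
#' they hold exactly.
#'
#' @param fit a `jm_fit`.
#' @return list with `dic`, `d_at_mean`, `p_d`, `d_bar`.
#' @export
dic <- function(fit) {
  pd <- p_d(fit)
  list(dic = pd$d_at_mean + 2 * pd$p_d, d_at_mean = pd$d_at_mean,
       p_d = pd$p_d, d_bar = pd$d_bar)
}

#' Log pseudo-marginal likelihood
#'
#' `sum_i log CPO_i`, where each conditional predictive ordinate is the
#' harmonic mean of the subject's per-draw conditional likelihood, computed
#' in log space with a max-shift for stability.
#'
#' @param fit a `jm_fit`.
#' @return scalar LPML.
#' @export
lpml <- function(fit) {
  stopifnot(inherits(fit, "jm_fit"))
  ll <- fit$ll_subj # draws x subjects
  neg <- -ll
  m <- apply(neg, 2L, max)
  # log mean exp of -ll per subject, then negate: log CPO_i
  lme <- m + log(colMeans(exp(sweep(neg, 2L, m))))
  sum(-lme)
}

#' Compare fitted association structures
#'
#' One row per fitted structure with the deviance at the posterior mean, pD,
#' DIC and LPML, ranked by ascending DIC (smaller is better); exact DIC ties
#' are broken by the order the fits were supplied. All fits must be on the
#' same dataset.
#'
#' @param fits named list of `jm_fit` objects (names default to each fit's
#'   structure tag).
#' @return object of class `jm_comparison`: a data.frame with attributes
#'   `selected` (the DIC-minimising structure).
#' @export
compare_structures <- function(fits) {
  if (inherits(fits, "jm_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, logical(1L),
                                           "jm_fit")))
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    names(fits) <- vapply(fits, function(f) f$structure$tag, character(1L))
  fps <- vapply(fits, `[[`, character(1L), "dataset_fingerprint")
  if (length(unique(fps)) != 1L)
    stop("fits were obtained on different datasets")
  rows <- lapply(fits, function(f) {
    d <- dic(f)
    data.frame(structure = f$structure$tag, d_at_mean = d$d_at_mean,
               p_d = d$p_d, dic = d$dic, lpml = lpml(f))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(fits)
  out <- out[order(out$dic, seq_len(nrow(out))), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  structure(out, class = c("jm_comparison", "data.frame"),
            selected = out$structure[1L])
}

#' @export
print.jm_comparison <- function(x, digits = 2L, ...) {
  cat("Association-structure comparison (DIC ascending):\n")
  print.data.frame(x, digits = digits + 4L)
  cat("\nSelected structure:", attr(x, "selected"), "\n")
  invisible(x)
}
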