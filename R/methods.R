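#' Posterior summary of a draws matrix
#'
#' Per column: posterior mean, SD and central 95% interval; optionally a
#' hazard-ratio style transform (`exp` by default) applied to selected
#' columns, with the transformed interval taken from the transformed
#' quantiles.
#'
#' @param draws numeric matrix, one column per scalar parameter.
#' @param transform monotone transform for the ratio columns (default `exp`).
#' @param transform_cols character vector of column names to transform;
#'   default: the log-hazard-ratio columns (`gamma_*`, `alpha*`).
#' @return data.frame with columns `mean`, `sd`, `q2.5`, `q97.5` and, for
#'   transformed rows, `ratio`, `ratio_lo`, `ratio_hi`.
#' @export
posterior_summary <- function(draws, transform = exp,
                              transform_cols = NULL) {
  draws <- as.matrix(draws)
  if (is.null(transform_cols))
    transform_cols <- grep("^(gamma_|alpha)", colnames(draws), value = TRUE)
  qs <- t(apply(draws, 2L, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE))
  out <- data.frame(mean = colMeans(draws), sd = apply(draws, 2L, stats::sd),
                    q2.5 = qs[, 1L], q97.5 = qs[, 2L],
                    row.names = colnames(draws))
  out$ratio <- out$ratio_lo <- out$ratio_hi <- NA_real_
  tc <- intersect(transform_cols, colnames(draws))
  if (length(tc)) {
    out[tc, "ratio"] <- transform(out[tc, "mean"])
    out[tc, "ratio_lo"] <- transform(out[tc, "q2.5"])
    out[tc, "ratio_hi"] <- transform(out[tc, "q97.5"])
  }
  out
}

#' @export
print.jm_fit <- function(x, digits = 3L, ...) {
  cat("Bayesian joint model (", x$structure$tag, " association)\n",
      "  ", x$n_subjects, " subjects, ",
      sum(x$dataset$survival$event), " events; ",
      max(x$chain_id), " chain(s), ", nrow(x$draws), " kept draws\n\n",
      sep = "")
  print(round(coef(x), digits))
  invisible(x)
}

#' @export
coef.jm_fit <- function(object, ...) colMeans(object$draws)

#' @export
summary.jm_fit <- function(object, ...) {
  tab <- posterior_summary(object$draws)
  hr <- tab[grep("^(gamma_|alpha)", rownames(tab)), ]
  hr_fmt <- sprintf("%.2f (%.2f-%.2f)", hr$ratio, hr$ratio_lo, hr$ratio_hi)
  names(hr_fmt) <- rownames(hr)
  structure(list(table = tab, hazard_ratios = hr_fmt,
                 structure = object$structure$tag,
                 n_draws = nrow(object$draws)),
            class = "summary.jm_fit")
}

#' @export
print.summary.jm_fit <- function(x, digits = 3L, ...) {
  cat("Joint model,", x$structure, "association;", x$n_draws,
      "posterior draws\n\nPosterior summaries:\n")
  print(round(x$table[, c("mean", "sd", "q2.5", "q97.5")], digits))
  cat("\nHazard ratios, HR (95% CI):\n")
  for (nm in names(x$hazard_ratios))
    cat(sprintf("  %-13s %s\n", nm, x$hazard_ratios[nm]))
  invisible(x)
}

#' @export
logLik.jm_fit <- function(object, ...) {
  structure(mean(object$ll_draws), class = "logLik",
            df = ncol(object$draws), nobs = object$n_subjects)
}

#' Traceplots of selected parameters
#'
#' @param x a `jm_fit`.
#' @param pars parameter names (default: the association and arm
#'   coefficients).
#' @param ... passed to [graphics::plot()].
#' @export
plot.jm_fit <- function(x, pars = c("alpha1", "gamma_arm"), ...) {
  pars <- intersect(pars, colnames(x$draws))
  old <- graphics::par(mfrow = c(length(pars), 1L), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(old))
  for (p in pars) {
    graphics::plot(x$draws[, p], type = "n", ylab = p, xlab = "", ...)
    for (ch in unique(x$chain_id)) {
      idx <- which(x$chain_id == ch)
      graphics::lines(idx - min(idx) + 1L, x$draws[idx, p], col = ch)
    }
  }
  invisible(x)
}

# --- convergence diagnostics ------------------------------------------------

.split_chains <- function(x, chain_id) {
  out <- list()
  for (ch in unique(chain_id)) {
    v <- x[chain_id == ch]
    h <- length(v) %/% 2L
    if (h < 2L) return(list(v))
    out <- c(out, list(v[seq_len(h)], v[(h + 1L):(2L * h)]))
  }
  out
}

.rhat <- function(chains) {
  m <- length(chains)
  n <- length(chains[[1L]])
  mu <- vapply(chains, mean, numeric(1L))
  s2 <- vapply(chains, stats::var, numeric(1L))
  W <- mean(s2)
  B <- n * stats::var(mu)
  if (W < .Machine$double.eps) return(1)
  # floored at 1: values below 1 are estimation noise, and byte-identical
  # chains then report exactly 1
  sqrt(max(1, ((n - 1) / n * W + B / n) / W))
}

.ess <- function(chains) {
  # Geyer initial-monotone-positive-sequence estimator on pooled
  # per-chain autocorrelations
  n <- length(chains[[1L]])
  m <- length(chains)
  W <- mean(vapply(chains, stats::var, numeric(1L)))
  if (W < .Machine$double.eps) return(NA_real_)
  maxlag <- min(n - 1L, 200L)
  if (maxlag < 2L) return(NA_real_)
  rho <- rowMeans(matrix(vapply(chains, function(v) {
    a <- stats::acf(v, lag.max = maxlag, plot = FALSE,
                    demean = TRUE)$acf[, 1L, 1L]
    a[-1L]
  }, numeric(maxlag)), maxlag, m))
  ssum <- 0
  t <- 1L
  while (t + 1L <= maxlag) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    ssum <- ssum + pair
    t <- t + 2L
  }
  m * n / (1 + 2 * ssum)
}

#' Convergence diagnostics
#'
#' Split-chain potential scale reduction (R-hat) and effective sample size
#' per scalar parameter; parameters with R-hat above 1.1 are flagged. With a
#' single short chain that cannot be split, R-hat is omitted with a warning.
#'
#' @param fit a `jm_fit` (or a draws matrix plus `chain_id`).
#' @param chain_id chain index per row when `fit` is a matrix.
#' @return data.frame with `parameter`, `rhat`, `ess`, `flagged`.
#' @export
diagnostics <- function(fit, chain_id = NULL) {
  if (inherits(fit, "jm_fit")) {
    draws <- fit$draws
    chain_id <- fit$chain_id
  } else {
    draws <- as.matrix(fit)
    if (is.null(chain_id)) chain_id <- rep(1L, nrow(draws))
  }
  single <- length(unique(chain_id)) == 1L && nrow(draws) < 4L
  if (single) warning("single short chain: R-hat omitted")
  out <- data.frame(parameter = colnames(draws), rhat = NA_real_,
                    ess = NA_real_, flagged = FALSE)
  for (j in seq_len(ncol(draws))) {
    ch <- .split_chains(draws[, j], chain_id)
    if (!single && length(ch) >= 2L) out$rhat[j] <- .rhat(ch)
    out$ess[j] <- .ess(ch)
  }
  out$flagged <- !is.na(out$rhat) & out$rhat > 1.1
  out
}
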