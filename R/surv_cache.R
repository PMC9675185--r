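# Internal vectorised survival-likelihood machinery.
#
# The MCMC sampler evaluates the survival likelihood thousands of times with
# fixed data, fixed quadrature layout and fixed basis matrices; only the
# parameters change.  build_surv_cache() precomputes every basis evaluation
# once; surv_loglik_cached() is then pure vector arithmetic.
#
# Outer rule: 15-point Gauss-Legendre on [0, T_i] (7 panels when
# T_i > 12 months).  For the weighted-cumulative structure the inner
# integral over elapsed time u = t - s uses a graded panelisation
# (0, 1, 4, 12, t months) with 7-point Gauss-Legendre per panel: the normal
# kernel always peaks at u = 0 and decays monotonically, so grading towards
# u = 0 resolves every kernel scale the sampler visits without
# sigma_w-dependent nodes.
#
# The association functional is linear in the per-subject coefficient rows
# (beta + b_i), and for the weighted structure it factorises into a
# coefficient part (trajectory at the inner nodes) and a kernel part
# (weights at the elapsed times).  The sampler exploits this: updates of
# (gamma, alpha, k) reuse the raw functional, updates of sigma_w reuse the
# trajectory part.

.inner_u_edges <- c(0, 1, 4, 12)

# cbind a constant column onto a possibly zero-row matrix without recycling
.cbind_const <- function(const, M) cbind(rep(const, nrow(M)), M)

build_surv_cache <- function(dataset, structure, bspec, ncs,
                             inner_points = 7L) {
  s <- dataset$survival
  n <- nrow(s)
  if (any(s$time <= 0)) stop("cached survival likelihood requires T > 0")
  node_t <- node_w <- numeric(0)
  node_subj <- integer(0)
  for (i in seq_len(n)) {
    q <- gauss_legendre_panels(15L, 0, s$time[i],
                               panels = if (s$time[i] > 12) 7L else 1L)
    node_t <- c(node_t, q$nodes)
    node_w <- c(node_w, q$weights)
    node_subj <- c(node_subj, rep.int(i, length(q$nodes)))
  }
  ev_idx <- which(s$event == 1)
  ev_t <- s$time[ev_idx]

  cache <- list(
    n = n, event = s$event, ev_idx = ev_idx,
    W = cbind(s$arm, s$age, s$gender),
    node_t = node_t, node_w = node_w, node_subj = node_subj,
    Xb_nodes = .baseline_design(node_t, bspec),
    Xb_ev = .baseline_design(ev_t, bspec),
    tag = structure$tag,
    t_max = if (!is.null(structure$weight)) structure$weight$t_max
  )

  design_for <- function(tt) switch(structure$tag,
    current_value = .cbind_const(1, ncs_basis(tt, ncs)),
    slopes = .cbind_const(1, ncs_basis(tt, ncs)),
    cumulative = cbind(tt, ncs_basis_integral(tt, ncs)),
    weighted_cumulative = NULL)
  cache$M_nodes <- design_for(node_t)
  cache$M_ev <- design_for(ev_t)
  if (structure$tag == "slopes") {
    cache$Md_nodes <- .cbind_const(0, ncs_basis_deriv(node_t, ncs))
    cache$Md_ev <- .cbind_const(0, ncs_basis_deriv(ev_t, ncs))
  }
  if (structure$tag == "weighted_cumulative") {
    base <- gauss_legendre(inner_points) # on [-1, 1]
    inner_for <- function(tt, subj) {
      iu <- iw <- numeric(0); iout <- integer(0)
      for (j in seq_along(tt)) {
        edges <- unique(c(.inner_u_edges[.inner_u_edges < tt[j]], tt[j]))
        for (e in seq_len(length(edges) - 1L)) {
          half <- (edges[e + 1L] - edges[e]) / 2
          iu <- c(iu, half * base$nodes + (edges[e] + edges[e + 1L]) / 2)
          iw <- c(iw, half * base$weights)
          iout <- c(iout, rep.int(j, inner_points))
        }
      }
      it <- tt[iout] - iu # inner time s = t - u
      list(u = iu, glw = iw, out = iout, subj = subj[iout],
           M = .cbind_const(1, ncs_basis(it, ncs)), n_points = length(tt))
    }
    cache$inner_nodes <- inner_for(node_t, node_subj)
    cache$inner_ev <- inner_for(ev_t, ev_idx)
  }
  cache
}

# kernel weight values without constructing a weight_spec
.wkernel <- function(u, sigma_w, t_max) {
  out <- stats::dnorm(u, 0, sigma_w) /
    (stats::pnorm(t_max, 0, sigma_w) - 0.5)
  out[u < 0 | u > t_max] <- 0
  out
}

.rowsum_full <- function(x, group, n) {
  out <- numeric(n)
  if (!length(group)) return(out)
  rs <- rowsum(x, group)
  out[as.integer(rownames(rs))] <- rs
  out
}

# The weighted area at outer node j is linear in that subject's coefficient
# row:  f_j = sum_q kw(u_q) M_q cf = G[j, ] . cf  with
# G = rowsum(kw * M, outer index).  G depends on sigma_w only, so
# coefficient updates cost the same as for the other structures and only
# sigma_w updates pay for the kernel re-aggregation.
.wa_G <- function(inner, sigma_w, t_max) {
  if (!length(inner$out)) return(matrix(0, 0L, ncol(inner$M)))
  kw <- inner$glw * .wkernel(inner$u, sigma_w, t_max)
  rowsum(kw * inner$M, inner$out)
}

# raw association functional (no alpha) at the outer nodes and event times;
# for weighted_cumulative the sigma_w-dependent aggregation G can be reused
.assoc_raw <- function(cache, coefs, sigma_w = NULL, G = NULL) {
  switch(cache$tag,
    current_value = ,
    cumulative = list(
      f_nodes = rowSums(cache$M_nodes *
                          coefs[cache$node_subj, , drop = FALSE]),
      f_ev = rowSums(cache$M_ev * coefs[cache$ev_idx, , drop = FALSE])),
    slopes = {
      cs_n <- coefs[cache$node_subj, , drop = FALSE]
      cs_e <- coefs[cache$ev_idx, , drop = FALSE]
      list(f_nodes = rowSums(cache$M_nodes * cs_n),
           f_ev = rowSums(cache$M_ev * cs_e),
           fd_nodes = rowSums(cache$Md_nodes * cs_n),
           fd_ev = rowSums(cache$Md_ev * cs_e))
    },
    weighted_cumulative = {
      if (is.null(G))
        G <- list(nodes = .wa_G(cache$inner_nodes, sigma_w, cache$t_max),
                  ev = .wa_G(cache$inner_ev, sigma_w, cache$t_max))
      list(
        f_nodes = rowSums(G$nodes * coefs[cache$node_subj, , drop = FALSE]),
        f_ev = rowSums(G$ev * coefs[cache$ev_idx, , drop = FALSE]),
        G = G)
    })
}

# splice the raw functional rows of the accepted subjects (logical vector a)
# from a proposal into the current raw state; the functional is per-subject,
# so rows belonging to rejected subjects keep their current values
.raw_splice <- function(cache, raw_cur, raw_p, a) {
  sel_n <- a[cache$node_subj]
  sel_e <- a[cache$ev_idx]
  raw_cur$f_nodes[sel_n] <- raw_p$f_nodes[sel_n]
  raw_cur$f_ev[sel_e] <- raw_p$f_ev[sel_e]
  if (cache$tag == "slopes") {
    raw_cur$fd_nodes[sel_n] <- raw_p$fd_nodes[sel_n]
    raw_cur$fd_ev[sel_e] <- raw_p$fd_ev[sel_e]
  }
  raw_cur
}

# per-subject survival log-likelihood: delta_i log h_i(T_i) - H_i(T_i);
# `raw` is the output of .assoc_raw (computed here when absent)
surv_loglik_cached <- function(cache, k, gamma, alpha1, alpha2, coefs,
                               sigma_w = NULL, raw = NULL) {
  if (is.null(raw)) raw <- .assoc_raw(cache, coefs, sigma_w)
  weta <- drop(cache$W %*% gamma)
  a_nodes <- alpha1 * raw$f_nodes
  a_ev <- alpha1 * raw$f_ev
  if (cache$tag == "slopes") {
    a_nodes <- a_nodes + alpha2 * raw$fd_nodes
    a_ev <- a_ev + alpha2 * raw$fd_ev
  }
  lh_nodes <- drop(cache$Xb_nodes %*% k) + weta[cache$node_subj] + a_nodes
  H <- .rowsum_full(cache$node_w * exp(lh_nodes), cache$node_subj, cache$n)
  ll <- -H
  if (length(cache$ev_idx)) {
    lh_ev <- drop(cache$Xb_ev %*% k) + weta[cache$ev_idx] + a_ev
    ll[cache$ev_idx] <- ll[cache$ev_idx] + lh_ev
  }
  ll
}

# longitudinal cache: fixed design, subject index and the per-subject
# sufficient statistics (X_i'X_i, X_i'y_i) used by the conjugate
# random-effect proposal
build_long_cache <- function(dataset, ncs) {
  long <- dataset$longitudinal
  idx <- match(long$subject_id, dataset$survival$subject_id)
  X <- cbind(1, ncs_basis(long$time, ncs))
  n <- nrow(dataset$survival)
  p <- ncol(X)
  XtX <- array(0, c(p, p, n))
  Xty <- matrix(0, n, p)
  for (i in seq_len(n)) {
    rows <- idx == i
    Xi <- X[rows, , drop = FALSE]
    XtX[, , i] <- crossprod(Xi)
    Xty[i, ] <- crossprod(Xi, long$y[rows])
  }
  list(y = long$y, idx = idx, X = X, n = n, XtX = XtX, Xty = Xty)
}

# Conjugate random-effect proposal: b_i* ~ N(m_i, V_i), the exact
# conditional of b_i given the longitudinal data, the current beta, sigma2
# and D. The Gaussian target factors cancel against the proposal density,
# so the Metropolis-Hastings ratio is the survival-likelihood ratio alone
# (and the update is an exact Gibbs step when the survival part is off).
# The 3x3 Cholesky solves are written out componentwise and vectorised over
# subjects; this runs every iteration for every subject.
propose_b_conjugate <- function(lc, beta, sigma2, Dinv, n, p) {
  if (p != 3L) stop("conjugate proposal assumes a 3-dimensional b")
  if (!is.null(lc)) {
    a11 <- lc$XtX[1, 1, ] / sigma2 + Dinv[1, 1]
    a21 <- lc$XtX[2, 1, ] / sigma2 + Dinv[2, 1]
    a31 <- lc$XtX[3, 1, ] / sigma2 + Dinv[3, 1]
    a22 <- lc$XtX[2, 2, ] / sigma2 + Dinv[2, 2]
    a32 <- lc$XtX[3, 2, ] / sigma2 + Dinv[3, 2]
    a33 <- lc$XtX[3, 3, ] / sigma2 + Dinv[3, 3]
    r1 <- (lc$Xty[, 1] - (lc$XtX[1, 1, ] * beta[1] +
                            lc$XtX[1, 2, ] * beta[2] +
                            lc$XtX[1, 3, ] * beta[3])) / sigma2
    r2 <- (lc$Xty[, 2] - (lc$XtX[2, 1, ] * beta[1] +
                            lc$XtX[2, 2, ] * beta[2] +
                            lc$XtX[2, 3, ] * beta[3])) / sigma2
    r3 <- (lc$Xty[, 3] - (lc$XtX[3, 1, ] * beta[1] +
                            lc$XtX[3, 2, ] * beta[2] +
                            lc$XtX[3, 3, ] * beta[3])) / sigma2
  } else {
    a11 <- rep(Dinv[1, 1], n); a21 <- rep(Dinv[2, 1], n)
    a31 <- rep(Dinv[3, 1], n); a22 <- rep(Dinv[2, 2], n)
    a32 <- rep(Dinv[3, 2], n); a33 <- rep(Dinv[3, 3], n)
    r1 <- r2 <- r3 <- numeric(n)
  }
  # lower-Cholesky of the per-subject precision A = L L'
  l11 <- sqrt(a11)
  l21 <- a21 / l11
  l31 <- a31 / l11
  l22 <- sqrt(a22 - l21^2)
  l32 <- (a32 - l31 * l21) / l22
  l33 <- sqrt(a33 - l31^2 - l32^2)
  # mean: solve L z = r, then L' m = z
  z1 <- r1 / l11
  z2 <- (r2 - l21 * z1) / l22
  z3 <- (r3 - l31 * z1 - l32 * z2) / l33
  m3 <- z3 / l33
  m2 <- (z2 - l32 * m3) / l22
  m1 <- (z1 - l21 * m2 - l31 * m3) / l11
  # sample: m + solve(L', e), e ~ N(0, I)
  e1 <- stats::rnorm(n); e2 <- stats::rnorm(n); e3 <- stats::rnorm(n)
  w3 <- e3 / l33
  w2 <- (e2 - l32 * w3) / l22
  w1 <- (e1 - l21 * w2 - l31 * w3) / l11
  cbind(m1 + w1, m2 + w2, m3 + w3)
}

# per-subject longitudinal log-likelihood
long_loglik_cached <- function(cache, coefs, sigma2_eps) {
  mu <- rowSums(cache$X * coefs[cache$idx, , drop = FALSE])
  .rowsum_full(stats::dnorm(cache$y, mu, sqrt(sigma2_eps), log = TRUE),
               cache$idx, cache$n)
}
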