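#' Gauss-Legendre nodes and weights
#'
#' Golub-Welsch construction: nodes are eigenvalues of the symmetric Jacobi
#' matrix of the Legendre recurrence, weights come from the first component of
#' the eigenvectors. Exact for polynomials of degree 2n - 1.
#'
#' @param n number of nodes.
#' @param a,b interval endpoints.
#' @return list with `nodes` and `weights`, both length `n`, on `[a, b]`.
#' @keywords internal
gauss_legendre <- function(n, a = -1, b = 1) {
  stopifnot(n >= 1, b >= a)
  if (n == 1L) {
    x <- 0
    w <- 2
  } else {
    i <- seq_len(n - 1L)
    off <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1L)] <- off
    J[cbind(i + 1L, i)] <- off
    e <- eigen(J, symmetric = TRUE)
    ord <- order(e$values)
    x <- e$values[ord]
    w <- 2 * e$vectors[1L, ord]^2
  }
  list(nodes = (b - a) / 2 * x + (a + b) / 2, weights = (b - a) / 2 * w)
}

# Panelised Gauss-Legendre rule on [a, b]: n-point rule on each of `panels`
# equal subintervals.  Returns concatenated nodes/weights.
gauss_legendre_panels <- function(n, a, b, panels = 1L) {
  if (panels <= 1L) return(gauss_legendre(n, a, b))
  edges <- seq(a, b, length.out = panels + 1L)
  base <- gauss_legendre(n) # on [-1, 1]
  half <- diff(edges) / 2
  mid <- (edges[-1L] + edges[-(panels + 1L)]) / 2
  list(
    nodes = as.vector(outer(base$nodes, half) + rep(mid, each = n)),
    weights = as.vector(outer(base$weights, half))
  )
}
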