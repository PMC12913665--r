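#' Euclidean k-nearest neighborhoods
#'
#' Self is excluded; distance ties are broken by the lower index.
#'
#' @param X `n x D` point matrix.
#' @param k neighborhood size, `1 <= k < n`.
#' @return `n x k` integer matrix of neighbor indices, nearest first.
#' @export
knn_neighborhoods <- function(X, k = 12) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k >= n) stop("k must be smaller than the number of points")
  if (k < 1) stop("k must be >= 1")
  D <- as.matrix(stats::dist(X))
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    idx[i, ] <- order(d, seq_len(n))[seq_len(k)]
  }
  idx
}

#' Local Hessian estimate from a quadratic fit in tangent coordinates
#'
#' Local PCA of the neighbor displacements gives a tangent basis; the
#' off-tangent residual magnitudes are fitted by ridge least squares with a
#' full quadratic model `c + b't + 0.5 t'Qt`; the symmetric coefficient
#' matrix `Q` is mapped back to the ambient space as `U Q U'`. Indefinite
#' results are shifted to positive semidefiniteness.
#'
#' @param x_i center point (length-D vector).
#' @param neighbors `k x D` matrix of neighbor coordinates.
#' @param d target tangent dimension; capped at `min(d, k - 1, D)`.
#' @param eps_H scale of the diagonal adjustment for degenerate or indefinite
#'   fits.
#' @return Symmetric positive semidefinite `D x D` matrix. The unadjusted fit
#'   is available as attribute `"raw"`.
#' @export
estimate_hessian <- function(x_i, neighbors, d = 2, eps_H = 1e-6) {
  neighbors <- as.matrix(neighbors)
  Dm <- ncol(neighbors)
  k <- nrow(neighbors)
  diffs <- sweep(neighbors, 2L, x_i)
  tot_var <- sum(diffs^2)
  if (tot_var < 1e-24) {
    H <- diag(eps_H, Dm)
    attr(H, "raw") <- matrix(0, Dm, Dm)
    return(H)
  }
  d_eff <- max(1L, min(d, k - 1L, Dm))
  sv <- svd(diffs, nu = 0, nv = d_eff)
  U <- sv$v                                   # D x d tangent basis
  Tc <- diffs %*% U                           # k x d tangent coordinates
  resid <- diffs - Tc %*% t(U)
  rho <- sqrt(rowSums(resid^2))               # off-tangent magnitude

  # design: 1, t_a, t_a t_b (a<b), 0.5 t_a^2
  quad_cols <- list()
  nm <- 0L
  if (d_eff >= 2) {
    for (a in seq_len(d_eff - 1L)) {
      for (b in (a + 1L):d_eff) {
        nm <- nm + 1L
        quad_cols[[nm]] <- Tc[, a] * Tc[, b]
      }
    }
  }
  design <- cbind(1, Tc,
                  if (nm > 0) do.call(cbind, quad_cols),
                  0.5 * Tc^2)
  XtX <- crossprod(design)
  lam <- 1e-6 * mean(diag(XtX))
  coef <- solve(XtX + diag(lam, ncol(design)), crossprod(design, rho))

  Q <- matrix(0, d_eff, d_eff)
  pos <- 1L + d_eff
  if (d_eff >= 2) {
    for (a in seq_len(d_eff - 1L)) {
      for (b in (a + 1L):d_eff) {
        pos <- pos + 1L
        Q[a, b] <- Q[b, a] <- coef[pos]
      }
    }
  }
  diag(Q) <- coef[(pos + 1L):(pos + d_eff)]
  H <- U %*% Q %*% t(U)
  H <- (H + t(H)) / 2
  raw <- H
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0) {
    H <- H + diag(-min(ev) + eps_H * max(abs(sum(diag(H))), 1) / d_eff, Dm)
  }
  attr(H, "raw") <- raw
  H
}

#' Hessian-weighted simplex-constrained reconstruction weights
#'
#' Minimizes `(x_i - sum_j w_j x_j)' H (x_i - sum_j w_j x_j)` subject to
#' `sum w = 1` and (optionally) `w >= 0`, via quadratic programming on the
#' ridge-stabilized Gram matrix `G = Delta H Delta'` with
#' `ridge = 1e-3 * trace(G) / k`.
#'
#' @param x_i center point.
#' @param neighbors `k x D` neighbor matrix.
#' @param H_i symmetric PSD weighting matrix (identity recovers the classical
#'   locally linear reconstruction).
#' @param nonneg enforce `w >= 0` (the default); with `FALSE` the closed-form
#'   equality-constrained solution is returned.
#' @param ridge_scale relative ridge on the Gram matrix.
#' @return Weight vector of length `k` summing to 1.
#' @export
reconstruction_weights <- function(x_i, neighbors, H_i = NULL, nonneg = TRUE,
                                   ridge_scale = 1e-3) {
  neighbors <- as.matrix(neighbors)
  k <- nrow(neighbors)
  if (k == 0) stop("neighborhood is empty")
  if (k == 1) return(1)
  if (is.null(H_i)) H_i <- diag(ncol(neighbors))
  Delta <- sweep(neighbors, 2L, x_i)
  G <- Delta %*% H_i %*% t(Delta)
  G <- (G + t(G)) / 2
  ridge <- ridge_scale * (sum(diag(G)) + 1e-12) / k
  G <- G + diag(ridge, k)
  if (!nonneg) {
    s <- solve(G, rep(1, k))
    return(as.vector(s / sum(s)))
  }
  sol <- quadprog::solve.QP(
    Dmat = 2 * G, dvec = rep(0, k),
    Amat = cbind(rep(1, k), diag(k)), bvec = c(1, rep(0, k)), meq = 1
  )
  w <- sol$solution
  w[w < 0 & w > -1e-12] <- 0
  as.vector(w / sum(w))
}

#' Embedding from a row-stochastic reconstruction-weight matrix
#'
#' Returns the bottom-`d` eigenvectors of `M = (I - W)'(I - W)`, excluding
#' the constant direction (which is deflated explicitly), minimizing
#' `sum_i ||y_i - sum_j w_ij y_j||^2`. Eigenvector signs are fixed by making
#' each column's largest-magnitude entry positive.
#'
#' @param W `n x n` weight matrix with rows summing to 1 (zeros outside each
#'   point's neighborhood).
#' @param d embedding dimension, `d < n`.
#' @return `n x d` matrix with orthonormal columns; attribute `"eigenvalues"`
#'   holds the corresponding eigenvalues of `M`.
#' @export
hlle_embed <- function(W, d) {
  W <- as.matrix(W)
  n <- nrow(W)
  if (d >= n) stop("embedding dimension must be smaller than n")
  stopifnot(max(abs(rowSums(W) - 1)) < 1e-6)
  IW <- diag(n) - W
  M <- crossprod(IW)
  # deflate the constant eigenvector so ties at eigenvalue 0 cannot leak it in
  shift <- sum(diag(M)) + 1
  Md <- M + shift * matrix(1 / n, n, n)
  es <- eigen(Md, symmetric = TRUE)
  sel <- seq(n, n - d + 1L)                    # d smallest of the deflated M
  Y <- es$vectors[, sel, drop = FALSE]
  vals <- es$values[sel]
  for (j in seq_len(d)) {
    i <- which.max(abs(Y[, j]))
    if (Y[i, j] < 0) Y[, j] <- -Y[, j]
  }
  attr(Y, "eigenvalues") <- vals
  Y
}

#' Hessian-weighted locally linear embedding
#'
#' Full pipeline: k-nearest neighborhoods, per-point Hessian estimates,
#' simplex-constrained Hessian-weighted reconstruction weights, and the
#' spectral embedding. Deterministic given the input order.
#'
#' @param X `n x D` data matrix (rows = points).
#' @param k neighborhood size (default 12).
#' @param d embedding dimension (default 64, capped to `n - 2`).
#' @param nonneg enforce nonnegative reconstruction weights.
#' @return Object of class `hlle`: list with `Y` (`n x d` embedding), `W`
#'   (weight matrix), `neighborhoods`, `k`, `d`.
#' @export
hlle_transform <- function(X, k = 12, d = 64, nonneg = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (!(n > k && k >= 1)) stop("need n > k >= 1")
  d <- min(d, n - 2L)
  nb <- knn_neighborhoods(X, k)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nbrs <- X[nb[i, ], , drop = FALSE]
    H <- estimate_hessian(X[i, ], nbrs, d = d)
    W[i, nb[i, ]] <- reconstruction_weights(X[i, ], nbrs, H, nonneg = nonneg)
  }
  Y <- hlle_embed(W, d)
  structure(list(Y = Y, W = W, neighborhoods = nb, k = k, d = d),
            class = "hlle")
}
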