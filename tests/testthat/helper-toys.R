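# Small hand-built fixtures shared across test files.

# A superpixel map constructed directly from a label matrix (bypassing SLIC).
manual_sp <- function(labels) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  ids <- sort(unique(as.vector(labels)))
  stopifnot(identical(ids, seq_along(ids) - 1L))
  n <- length(ids)
  centers <- t(vapply(ids, function(j) {
    pos <- which(labels == j, arr.ind = TRUE)
    c(mean(pos[, 1L]), mean(pos[, 2L]))
  }, c(0, 0)))
  structure(list(labels = labels, n_nodes = n, seed_index = seq_len(n),
                 centers = centers, n_seeds = n),
            class = "superpixel_map")
}

# Straight-line (explicit loop) reference for one graph-conv layer.
loop_graph_conv <- function(A, X, W, slope = 0.01) {
  n <- nrow(A); dout <- ncol(W)
  out <- matrix(0, n, dout)
  for (i in seq_len(n)) {
    agg <- rep(0, ncol(X))
    for (j in seq_len(n)) agg <- agg + A[i, j] * X[j, ]
    for (c in seq_len(dout)) {
      s <- sum(agg * W[, c])
      out[i, c] <- if (s >= 0) s else slope * s
    }
  }
  out
}

# Explicit-loop affinity + symmetric normalization (independent of the
# package's vectorized path).
loop_normalized_adjacency <- function(X) {
  n <- nrow(X)
  Phi <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      Phi[i, j] <- exp(-sum(abs(X[i, ] - X[j, ])))
    }
  }
  d <- rep(0, n)
  for (i in seq_len(n)) d[i] <- sum(Phi[i, ])
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      A[i, j] <- Phi[i, j] / sqrt(d[i] * d[j])
    }
  }
  A
}

# Random small graph for equivariance checks.
random_toy_graph <- function(n = 6L, C = 5L, seed = 1L) {
  set.seed(seed)
  X <- matrix(rnorm(n * C), n, C)
  list(X = X, A1 = normalize_adjacency(build_affinity(X)))
}

perm_matrix <- function(perm) {
  n <- length(perm)
  P <- matrix(0, n, n)
  P[cbind(seq_len(n), perm)] <- 1
  P
}

fd_gradient <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    (f(x1) - f(x2)) / (2 * eps)
  }, 0)
}
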