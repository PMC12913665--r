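test_that("k-nearest neighborhoods match brute force with index tie-breaks", {
  # three collinear equally spaced points: the middle one ties, lower index wins
  X <- matrix(c(0, 1, 2), 3, 1)
  nb <- knn_neighborhoods(X, 1)
  expect_equal(nb[2, ], 1L)

  Xr <- matrix(rnorm(10 * 2), 10, 2)
  nb_all <- knn_neighborhoods(Xr, 9)
  for (i in 1:10) expect_setequal(nb_all[i, ], setdiff(1:10, i))

  set.seed(201)
  X50 <- matrix(rnorm(50 * 2), 50, 2)
  nb5 <- knn_neighborhoods(X50, 5)
  D <- as.matrix(dist(X50)); diag(D) <- Inf
  for (i in 1:50) expect_equal(nb5[i, ], order(D[i, ], seq_len(50))[1:5])

  expect_error(knn_neighborhoods(X, 3), "smaller")
})

test_that("Hessian estimates vanish on flat patches and recover curvature", {
  set.seed(202)
  flat <- cbind(runif(20), runif(20), 0)
  H <- estimate_hessian(c(0.5, 0.5, 0), flat, d = 2)
  expect_lt(max(abs(attr(H, "raw"))), 1e-8)

  # points on z = x^2 near the origin: second derivative 2
  x <- seq(-0.2, 0.2, length.out = 16); x <- x[abs(x) > 1e-9]
  H2 <- estimate_hessian(c(0, 0), cbind(x, x^2), d = 1)
  lead <- max(eigen(attr(H2, "raw"), symmetric = TRUE)$values)
  expect_lt(abs(lead - 2) / 2, 0.05)

  for (rep in 1:5) {
    pts <- matrix(rnorm(12 * 3), 12, 3)
    Hr <- estimate_hessian(rnorm(3), pts, d = 2)
    expect_equal(Hr, t(Hr), tolerance = 1e-12, ignore_attr = TRUE)
    expect_gte(min(eigen(Hr, symmetric = TRUE)$values), -1e-12)
  }

  # degenerate neighborhood (zero variance) falls back to a scaled identity
  Hd <- estimate_hessian(c(1, 1), matrix(1, 5, 2), d = 1)
  expect_equal(Hd, diag(1e-6, 2), ignore_attr = TRUE)
})

test_that("reconstruction weights solve the simplex-constrained problem", {
  expect_equal(reconstruction_weights(c(0), matrix(5, 1, 1)), 1)

  w_mid <- reconstruction_weights(0.5, matrix(c(0, 1), 2, 1), diag(1))
  expect_equal(w_mid, c(0.5, 0.5), tolerance = 1e-9)

  w_q <- reconstruction_weights(0.25, matrix(c(0, 1), 2, 1), diag(1))
  # grid-search oracle over the 1-simplex for the same ridge-stabilized form
  grid <- seq(0, 1, by = 1e-4)
  Delta <- c(-0.25, 0.75)
  G <- outer(Delta, Delta)
  G <- G + diag(1e-3 * sum(diag(G)) / 2, 2)
  vals <- vapply(grid, function(w1) {
    w <- c(w1, 1 - w1); as.numeric(t(w) %*% G %*% w)
  }, 0)
  expect_equal(w_q[1], grid[which.min(vals)], tolerance = 2e-4)
  expect_equal(w_q[1], 0.75, tolerance = 1e-3)
})

test_that("identity Hessian without nonnegativity recovers classical LLE", {
  set.seed(203)
  X <- matrix(rnorm(20 * 3), 20, 3)
  nb <- knn_neighborhoods(X, 6)
  for (i in c(1, 7, 15)) {
    nbrs <- X[nb[i, ], , drop = FALSE]
    w <- reconstruction_weights(X[i, ], nbrs, diag(3), nonneg = FALSE)
    Delta <- sweep(nbrs, 2, X[i, ])
    G <- Delta %*% t(Delta)
    G <- G + diag(1e-3 * sum(diag(G)) / 6, 6)
    w_ref <- solve(G, rep(1, 6)); w_ref <- w_ref / sum(w_ref)
    expect_equal(w, as.vector(w_ref), tolerance = 1e-6)
  }
})

test_that("weight rows sum to one and stay nonnegative through the pipeline", {
  set.seed(204)
  X <- matrix(rnorm(40 * 3), 40, 3)
  h <- hlle_transform(X, k = 8, d = 2)
  expect_true(all(abs(rowSums(h$W) - 1) < 1e-9))
  expect_true(all(h$W >= -1e-12))
})

test_that("embedding cost equals the selected eigenvalues of M", {
  set.seed(205)
  X <- matrix(rnorm(25 * 3), 25, 3)
  h <- hlle_transform(X, k = 6, d = 2)
  cost <- sum((h$Y - h$W %*% h$Y)^2)
  # dense independent oracle
  M <- crossprod(diag(25) - h$W)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(cost, sum(attr(h$Y, "eigenvalues")), tolerance = 1e-8)
  expect_equal(sort(attr(h$Y, "eigenvalues")), sort(ev)[2:3], tolerance = 1e-8)
  expect_equal(crossprod(h$Y), diag(2), tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(hlle_embed(h$W, 25), "smaller")
})

test_that("collinear points embed in arc-length order", {
  set.seed(206)
  # irregular but well-separated arc-length positions (order recovery is
  # only well-posed when no two points nearly coincide)
  tpar <- cumsum(runif(30, 0.5, 1.5)); tpar <- tpar / max(tpar)
  pts <- cbind(1 + 2 * tpar, -1 + 0.5 * tpar, tpar)
  h <- hlle_transform(pts, k = 5, d = 1)
  expect_equal(abs(cor(h$Y[, 1], tpar, method = "spearman")), 1)

  # away from the curve ends (whose neighborhoods are one-sided) the exact
  # ordering is recovered for any instance
  for (s in c(3, 5)) {
    set.seed(s)
    tp <- cumsum(runif(30, 0.5, 1.5)); tp <- tp / max(tp)
    hp <- hlle_transform(cbind(1 + 2 * tp, -1 + 0.5 * tp, tp), k = 5, d = 1)
    r <- rank(hp$Y[, 1])
    if (r[15] > 15) r <- 31 - r # orientation is arbitrary
    expect_identical(r[3:28], as.numeric(3:28))
  }
})

test_that("flat 2-D interior points are reconstructed exactly", {
  g <- expand.grid(x = 1:6, y = 1:6)
  X <- as.matrix(g)
  h <- hlle_transform(X, k = 4, d = 2)
  interior <- which(g$x %in% 2:5 & g$y %in% 2:5)
  resid <- sqrt(rowSums((X - h$W %*% X)^2))
  expect_lt(max(resid[interior]), 1e-6)
})

test_that("duplicated points embed identically and runs are bit-stable", {
  set.seed(207)
  X <- matrix(rnorm(20 * 3), 20, 3)
  X <- rbind(X, X[4, ]) # duplicate of point 4 at index 21
  h1 <- hlle_transform(X, k = 5, d = 2)
  h2 <- hlle_transform(X, k = 5, d = 2)
  expect_identical(h1$Y, h2$Y)
  expect_lt(max(abs(h1$Y[4, ] - h1$Y[21, ])), 1e-6)
})

test_that("the embedding is invariant to rigid rotation up to Procrustes", {
  set.seed(208)
  X <- matrix(rnorm(22 * 3), 22, 3)
  qrR <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(qrR) < 0) qrR[, 1] <- -qrR[, 1]
  h1 <- hlle_transform(X, k = 6, d = 2)
  h2 <- hlle_transform(X %*% qrR, k = 6, d = 2)
  sv <- svd(crossprod(h2$Y, h1$Y))
  Q <- sv$u %*% t(sv$v)
  expect_lt(max(abs(h1$Y - h2$Y %*% Q)), 1e-6)
})
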