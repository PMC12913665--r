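test_that("attention weights are softmax-normalized channel scores", {
  X <- matrix(c(4, 8), 1, 2)

  # H_a = 0 makes every score row zero, hence uniform attention
  p0 <- list(W_a = matrix(0, 3, 2), b_a = rep(0, 3), H_a = matrix(0, 2, 3))
  a0 <- attention_scores(X, p0)
  expect_equal(a0$alpha, matrix(0.5, 1, 2))

  # crafted params give u = (ln 3, 0) -> alpha = (0.75, 0.25)
  p1 <- list(W_a = matrix(0, 1, 2), b_a = atanh(0.5),
             H_a = matrix(c(2 * log(3), 0), 2, 1))
  a1 <- attention_scores(X, p1)
  expect_equal(as.vector(a1$u), c(log(3), 0), tolerance = 1e-12)
  expect_equal(as.vector(a1$alpha), c(0.75, 0.25), tolerance = 1e-12)

  set.seed(21)
  Xr <- matrix(rnorm(40), 8, 5)
  pr <- list(W_a = matrix(rnorm(20), 4, 5), b_a = rnorm(4),
             H_a = matrix(rnorm(20), 5, 4))
  ar <- attention_scores(Xr, pr)
  expect_true(all(abs(rowSums(ar$alpha) - 1) < 1e-9))
  expect_true(all(ar$alpha >= 0))
})

test_that("attribute enhancement is elementwise modulation with residual", {
  expect_true(all(enhance_attributes(matrix(0, 3, 2), matrix(0.5, 3, 2)) == 0))

  X <- matrix(2, 2, 4)
  expect_equal(enhance_attributes(X, matrix(0.25, 2, 4)), (1 + 1 / 4) * X)

  expect_equal(as.vector(enhance_attributes(matrix(c(4, 8), 1, 2),
                                            matrix(c(0.75, 0.25), 1, 2))),
               c(7, 10))
})

test_that("first encoder layer is LeakyReLU(A X W)", {
  X <- matrix(abs(rnorm(12)), 4, 3)
  expect_equal(encode_first_layer(diag(4), X, diag(3)), X)
  expect_true(all(encode_first_layer(diag(4), X * 0, diag(3)) == 0))

  A <- matrix(c(2 / 3, 1 / 3, 1 / 3, 2 / 3), 2, 2)
  Xt <- matrix(c(1, -1), 2, 1)
  Y <- encode_first_layer(A, Xt, matrix(1, 1, 1), slope = 0.01)
  expect_equal(as.vector(Y), c(1 / 3, -1 / 3 * 0.01), tolerance = 1e-12)
})

test_that("topology evolution concatenates channels and renormalizes", {
  Yp <- matrix(1, 3, 2); Xt <- matrix(2, 3, 4)
  A <- evolve_topology(Yp, Xt)
  expect_equal(ncol(attr(A, "Ytilde")), 6L)
  expect_equal(matrix(A, 3, 3), matrix(1 / 3, 3, 3), tolerance = 1e-12)

  # rows at L1 distance ln 2 give the 2/3-1/3 adjacency
  Y2 <- matrix(c(0, log(2)), 2, 1)
  X2 <- matrix(1, 2, 1)
  A2 <- evolve_topology(Y2, X2)
  expect_equal(matrix(A2, 2, 2),
               matrix(c(2 / 3, 1 / 3, 1 / 3, 2 / 3), 2, 2), tolerance = 1e-12)
})

test_that("encoder matches the single-layer op and a loop-based reference", {
  set.seed(31)
  X <- matrix(rnorm(15), 3, 5)
  A1 <- normalize_adjacency(build_affinity(X))

  m1 <- new_dgc_model(5, enc_widths = 4L, dec_width = 3L, seed = 7)
  att <- attention_scores(X, m1$params)
  Xt <- enhance_attributes(X, att$alpha)
  enc1 <- dgc_encode(Xt, A1, m1)
  expect_equal(enc1$Z, encode_first_layer(A1, Xt, m1$params$W1))

  expect_true(all(dgc_encode(Xt * 0, A1, m1)$Z == 0))

  # two-layer encoder vs an independent explicit-loop implementation
  m2 <- new_dgc_model(5, enc_widths = c(4L, 3L), dec_width = 3L, seed = 7)
  enc2 <- dgc_encode(Xt, A1, m2)
  Y1_ref <- loop_graph_conv(A1, Xt, m2$params$W1)
  A2_ref <- loop_normalized_adjacency(cbind(Y1_ref, Xt))
  Y2_ref <- loop_graph_conv(A2_ref, Y1_ref, m2$params$W2)
  expect_equal(enc2$Z, Y2_ref, tolerance = 1e-10)
})

test_that("decoding paints masks constant per superpixel and round-trips", {
  labels <- matrix(rep(0:3, each = 4), 4, 4)
  sp <- manual_sp(labels)

  painted <- paint_nodes(c(1L, 0L, 1L, 0L), sp)
  for (j in 0:3) expect_length(unique(painted[labels == j]), 1L)
  expect_equal(pool_mask_majority(painted, sp), c(1L, 0L, 1L, 0L))

  set.seed(5)
  node_lab <- sample(0:1, 4, replace = TRUE)
  expect_equal(pool_mask_majority(paint_nodes(node_lab, sp), sp),
               as.integer(node_lab))

  expect_true(all(paint_nodes(rep(1L, 4), sp) == 1L))
})

test_that("decoder output has node probabilities in [0, 1]", {
  set.seed(32)
  X <- matrix(rnorm(6 * 32), 6, 32)
  A1 <- normalize_adjacency(build_affinity(X))
  model <- new_dgc_model(32, seed = 1)
  att <- attention_scores(X, model$params)
  enc <- dgc_encode(enhance_attributes(X, att$alpha), A1, model)
  out <- dgc_decode(enc, model)
  expect_true(all(out$node_prob > 0 & out$node_prob < 1))
  expect_true(all(out$node_labels %in% 0:1))
})

test_that("segmentation loss combines BCE and soft-Dice correctly", {
  labels <- matrix(rep(0:3, each = 4), 4, 4)
  sp <- manual_sp(labels)
  gt <- paint_nodes(c(1L, 1L, 0L, 0L), sp)

  half <- list(node_prob = rep(0.5, 4))
  l <- segmentation_loss(half, gt, sp)
  expect_equal(l$bce, log(2), tolerance = 1e-6)
  expect_gte(l$dice_term, 0); expect_lte(l$dice_term, 1)

  perfect <- list(node_prob = c(1, 1, 0, 0))
  lp <- segmentation_loss(perfect, gt, sp)
  expect_lt(lp$bce, 1e-5)
  expect_lt(lp$dice_term, 0.1) # smoothing keeps it near but not at 0

  expect_error(segmentation_loss(half, gt * 0.5, sp), "binary")
})

test_that("encoder is permutation equivariant on random graphs", {
  for (seed in 1:3) {
    g <- random_toy_graph(6, 5, seed)
    model <- new_dgc_model(5, enc_widths = c(4L, 4L), dec_width = 3L, seed = seed)
    att <- attention_scores(g$X, model$params)
    Xt <- enhance_attributes(g$X, att$alpha)

    perm <- sample(6)
    P <- perm_matrix(perm)
    Xp <- g$X[perm, , drop = FALSE]
    attp <- attention_scores(Xp, model$params)
    Xtp <- enhance_attributes(Xp, attp$alpha)
    A1p <- normalize_adjacency(build_affinity(Xp))

    Z <- dgc_encode(Xt, g$A1, model)$Z
    Zp <- dgc_encode(Xtp, A1p, model)$Z
    expect_equal(Zp, P %*% Z, tolerance = 1e-9)
  }
})

test_that("analytic segmentation gradients match finite differences", {
  set.seed(42)
  ns <- asNamespace("gplnd")
  N <- 4; C <- 5
  X <- matrix(rnorm(N * C), N, C)
  A1 <- normalize_adjacency(build_affinity(X))
  model <- new_dgc_model(C, enc_widths = c(6L, 7L), dec_width = 5L,
                         att_hidden = 4L, seed = 3)
  g_nodes <- c(1, 0, 1, 0)
  sizes <- c(10, 12, 8, 9)
  gpix <- g_nodes * sizes

  fwd <- ns$dgc_forward_full(model, X, A1)
  res <- ns$dgc_loss_grad(model, fwd, g_nodes, sizes, gpix)
  adj_fixed <- fwd$A_raw

  flat <- ns$flatten_params(model$params)
  gflat <- ns$flatten_params(res$grads)
  lossfun <- function(vec) {
    m <- model
    m$params <- ns$unflatten_params(vec, model$params)
    f <- ns$dgc_forward_full(m, X, A1, adjacencies = adj_fixed)
    ns$dgc_loss_grad(m, f, g_nodes, sizes, gpix)$loss
  }
  idx <- sort(sample(length(flat), 30))
  # always include entries of W1, the first-layer weights
  w1_off <- length(model$params$W_a) + length(model$params$b_a) +
    length(model$params$H_a)
  idx <- sort(unique(c(idx, w1_off + 1:5)))
  fd <- vapply(idx, function(i) {
    p1 <- flat; p1[i] <- p1[i] + 1e-6
    p2 <- flat; p2[i] <- p2[i] - 1e-6
    (lossfun(p1) - lossfun(p2)) / 2e-6
  }, 0)
  relerr <- abs(fd - gflat[idx]) / pmax(abs(fd) + abs(gflat[idx]), 1e-8)
  expect_lt(max(relerr), 1e-4)
})

test_that("with uniform attention the first layer reduces to a scaled GCN", {
  set.seed(33)
  C <- 6
  X <- matrix(rnorm(4 * C), 4, C)
  A1 <- normalize_adjacency(build_affinity(X))
  model <- new_dgc_model(C, enc_widths = 4L, dec_width = 3L, seed = 2)
  model$params$H_a <- model$params$H_a * 0 # forces uniform alpha = 1/C

  att <- attention_scores(X, model$params)
  Xt <- enhance_attributes(X, att$alpha)
  Y <- dgc_encode(Xt, A1, model)$Z
  Y_ref <- encode_first_layer(A1, (1 + 1 / C) * X, model$params$W1)
  expect_equal(Y, Y_ref, tolerance = 1e-12)
})
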