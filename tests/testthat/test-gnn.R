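test_that("mean aggregation includes self and ignores neighbor order", {
  expect_equal(mean_aggregate(c(1, 2), NULL), c(1, 2))
  expect_equal(mean_aggregate(0, rbind(2, 4)), 2)

  set.seed(301)
  h <- rnorm(4)
  nb <- matrix(rnorm(12), 3, 4)
  expect_equal(mean_aggregate(h, nb), mean_aggregate(h, nb[c(3, 1, 2), ]))
})

test_that("gnn layer matches a hand-unrolled per-node loop", {
  H <- matrix(abs(rnorm(8)), 4, 2)
  P_iso <- aggregation_matrix(4, matrix(0, 0, 2))
  expect_equal(gnn_layer(H, P_iso, diag(2)), H)
  expect_true(all(gnn_layer(H * 0, P_iso, diag(2)) == 0))

  # 3-node path graph, scalar features, W = [1]
  h <- c(1, 2, 4)
  P <- aggregation_matrix(3, rbind(c(1, 2), c(2, 3)))
  got <- gnn_layer(matrix(h, 3, 1), P, matrix(1, 1, 1))
  want <- c(mean(c(1, 2)), mean(c(1, 2, 4)), mean(c(2, 4)))
  expect_equal(as.vector(got), want)
})

test_that("edge selection thresholds exactly and nests", {
  E <- rbind(c(1, 2), c(2, 3), c(3, 4))
  S <- c(0.9, 0.2, 0.5)
  expect_equal(nrow(select_edges(E, S, -Inf)), 3L)
  expect_equal(nrow(select_edges(E, S, max(S))), 0L)
  expect_equal(select_edges(E, S, 0.4), E[c(1, 3), ])

  set.seed(302)
  taus <- sort(runif(5))
  prev <- select_edges(E, S, -Inf)
  for (tau in taus) {
    cur <- select_edges(E, S, tau)
    expect_true(all(apply(cur, 1, paste, collapse = "-") %in%
                      apply(prev, 1, paste, collapse = "-")))
    prev <- cur
  }
})

test_that("readout pools node representations as documented", {
  expect_equal(readout(matrix(c(3, 1), 1, 2)), c(3, 1))
  expect_equal(readout(matrix(2, 5, 3)), rep(2, 3))
  expect_equal(readout(matrix(c(1, 3), 2, 1)), 2)
  expect_equal(readout(matrix(c(1, 3), 2, 1), "sum"), 4)
  # zero attention scores reduce to the mean
  expect_equal(readout(matrix(c(1, 3), 2, 1), "attention", w_att = 0), 2)
  expect_error(readout(matrix(0, 0, 2)), "empty")
})

test_that("the MLP head produces softmax probabilities", {
  head0 <- list(W1 = matrix(0, 2, 3), b1 = rep(0, 2),
                W2 = matrix(0, 2, 2), b2 = rep(0, 2))
  expect_equal(mlp_predict(rnorm(3), head0)$prob, c(0.5, 0.5))

  head1 <- list(W1 = diag(2), b1 = rep(0, 2),
                W2 = diag(2), b2 = c(log(3), 0))
  p <- mlp_predict(c(0, 0), head1)
  expect_equal(p$logits, c(log(3), 0))
  expect_equal(p$prob, c(0.75, 0.25), tolerance = 1e-12)

  set.seed(303)
  for (rep in 1:5) {
    head <- list(W1 = matrix(rnorm(8), 4, 2), b1 = rnorm(4),
                 W2 = matrix(rnorm(8), 2, 4), b2 = rnorm(2))
    pr <- mlp_predict(rnorm(2), head)$prob
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_true(all(pr >= 0))
  }
})

test_that("the total loss decomposes exactly into task and sparsity terms", {
  expect_equal(total_loss(c(0.5, 0.5), c(1, 0))$classification, log(2),
               tolerance = 1e-12)
  expect_lt(total_loss(c(1, 0), c(1, 0))$classification, 1e-11)

  st <- new_prune_state(4, 6, 3)
  st$m_a <- c(0.5, -0.25, 0, 1, 2, 0.75)
  st$m_x <- c(1, -1, 0.5)
  lt <- total_loss(c(0.3, 0.7), c(0, 1), st, lambda = 0.37)
  expect_identical(lt$total - lt$classification, 0.37 * lt$cgp)
  expect_equal(lt$cgp, mean(abs(c(st$m_a, st$m_x))))
  expect_equal(total_loss(c(0.3, 0.7), c(0, 1), st, lambda = 0)$total,
               total_loss(c(0.3, 0.7), c(0, 1))$total)
})

test_that("the full forward pass is invariant to node relabeling", {
  set.seed(304)
  ns <- asNamespace("gplnd")
  for (rep in 1:3) {
    n <- 6
    H0 <- matrix(rnorm(n * 4), n, 4)
    edges <- rbind(c(1, 2), c(2, 3), c(4, 5), c(5, 6), c(1, 6))
    gm <- new_gnn_model(4, hidden = 5, L = 3, seed = rep)
    P <- aggregation_matrix(n, edges)
    out <- ns$gnn_forward(gm, H0, P)

    perm <- sample(n)
    inv <- order(perm)
    edges_p <- matrix(inv[edges], ncol = 2)
    Pp <- aggregation_matrix(n, edges_p)
    out_p <- ns$gnn_forward(gm, H0[perm, ], Pp)
    expect_equal(out_p$prob, out$prob, tolerance = 1e-9)
    expect_equal(out_p$hG, out$hG, tolerance = 1e-9)
  }
})

test_that("classifier gradients match finite differences", {
  set.seed(305)
  ns <- asNamespace("gplnd")
  H0 <- matrix(rnorm(4 * 6), 4, 6)
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4))
  gm <- new_gnn_model(6, hidden = 5, L = 3, seed = 9)
  P <- aggregation_matrix(4, edges, c(0.9, 0.7, 1.1))
  y <- c(0, 1)

  fwd <- ns$gnn_forward(gm, H0, P)
  res <- ns$gnn_loss_grad(gm, fwd, y)
  flat <- ns$flatten_params(gm$params)
  gfl <- ns$flatten_params(res$grads)
  lf <- function(vec) {
    m <- gm; m$params <- ns$unflatten_params(vec, gm$params)
    total_loss(ns$gnn_forward(m, H0, P)$prob, y)$classification
  }
  idx <- sort(sample(length(flat), 40))
  fd <- vapply(idx, function(i) {
    p1 <- flat; p1[i] <- p1[i] + 1e-6
    p2 <- flat; p2[i] <- p2[i] - 1e-6
    (lf(p1) - lf(p2)) / 2e-6
  }, 0)
  relerr <- abs(fd - gfl[idx]) / pmax(abs(fd) + abs(gfl[idx]), 1e-8)
  expect_lt(max(relerr), 1e-4)
})

test_that("the classifier overfits a two-tile dataset and is seed-stable", {
  set.seed(306)
  mk_tile <- function(label, shift) {
    list(H0 = matrix(rnorm(3 * 4, mean = shift), 3, 4),
         edges = rbind(c(1, 2), c(2, 3)), pidx = c(1L, 2L), label = label)
  }
  ds <- list(mk_tile(0L, -1), mk_tile(1L, 1))
  fit <- train_classifier(ds, d_in = 4, epochs = 25L, lr = 5e-2,
                          batch_size = 2L, seed = 7)
  expect_lt(utils::tail(fit$history$train_loss, 1), fit$history$train_loss[1])

  fit2 <- train_classifier(ds, d_in = 4, epochs = 25L, lr = 5e-2,
                           batch_size = 2L, seed = 7)
  expect_identical(fit$history, fit2$history)
  expect_error(train_classifier(list(), d_in = 4), "empty")
})

test_that("well-separated Gaussian classes are classified above 0.95", {
  set.seed(307)
  n <- 200
  labels <- rep(0:1, each = n / 2)
  feats <- matrix(rnorm(n * 8), n, 8)
  feats[labels == 1, 1:2] <- feats[labels == 1, 1:2] + 6 # 6-sigma separation
  ds <- lapply(seq_len(n), function(i) {
    list(H0 = matrix(feats[i, ], 1, 8), edges = matrix(0, 0, 2),
         pidx = integer(0), label = labels[i])
  })
  idx <- sample(n)
  train <- idx[1:150]; test <- idx[151:200]
  fit <- train_classifier(ds[train], d_in = 8, epochs = 15L, lr = 2e-2,
                          batch_size = 8L, patience = Inf, seed = 11)
  preds <- vapply(test, function(i) predict_classifier(fit, ds[[i]])$label, 1L)
  expect_gte(mean(preds == labels[test]), 0.95)
})
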