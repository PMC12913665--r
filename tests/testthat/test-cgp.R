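test_that("topk_smallest matches a full-sort oracle including ties", {
  expect_identical(topk_smallest(c(3, -1, 2, -5), 0L), integer(0))
  expect_equal(topk_smallest(c(3, -1, 2, -5), 2), c(2L, 3L))
  expect_equal(topk_smallest(rep(1, 5), 2), c(1L, 2L))
  expect_error(topk_smallest(1:3, 4), "range")

  set.seed(101)
  for (rep in 1:1000) {
    n <- sample(1:30, 1)
    v <- round(rnorm(n), 1) # coarse rounding produces frequent ties
    K <- sample(0:n, 1)
    got <- topk_smallest(v, K)
    ord <- order(abs(v), seq_len(n)) # stable full sort
    expect_identical(sort(got), sort(ord[seq_len(K)]))
  }
})

test_that("retained-parameter arithmetic reproduces the pruning table", {
  expect_identical(count_retained(1967616, 0.50), 983808L)
  expect_identical(count_retained(1967616, 0.75), 491904L)
  expect_identical(count_retained(17, 0.3), 11L) # ceil(5.1) = 6 pruned
  expect_identical(count_retained(100, 0), 100L)
})

test_that("pruning achieves exact cardinalities", {
  pw <- prune_weights(c(3, -1, 2, -5), p_w = 0.5)
  expect_equal(pw$m_w, c(1, 0, 0, 1))
  expect_equal(pw$w, c(3, 0, 0, -5))

  pe <- prune_edges(c(0.9, 0.1, 0.5, 0.4), 0.5)
  expect_equal(pe$idx, c(2L, 4L))
  expect_equal(pe$m_a, c(0.9, 0, 0.5, 0))
  expect_equal(prune_edges(c(0.9, 0.1, 0.5, 0.4), 0)$n_retained, 4L)

  px <- prune_features(c(1.0, 0.2, 0.6, 0.3), 0.25, d = 4)
  expect_equal(px$idx, 2L)
  expect_error(prune_features(rep(1, 3), 0.5, d = 4), "d")

  pe17 <- prune_edges(runif(17, 0.1, 1), 0.3)
  expect_equal(pe17$n_retained, 11L)

  set.seed(102)
  for (rep in 1:1000) {
    n <- sample(1:10000, 1)
    p <- sample(0:999, 1) / 1000
    v <- rnorm(n)
    got <- prune_edges(v, p)$n_retained
    expect_identical(got, count_retained(n, p))
  }
})

test_that("pruning twice at the same rate is idempotent", {
  set.seed(103)
  v <- rnorm(50)
  p1 <- prune_edges(v, 0.4)
  p2 <- prune_edges(p1$m_a, 0.4)
  expect_identical(p2$m_a, p1$m_a)

  w <- rnorm(30)
  q1 <- prune_weights(w, p_w = 0.6)
  q2 <- prune_weights(q1$w, q1$m_w, 0.6)
  expect_identical(q2$m_w, q1$m_w)
  expect_identical(q2$w, q1$w)
})

test_that("the cubic schedule hits its endpoints and interior values", {
  s <- prune_schedule(p_f = 0.8, p_i = 0, t0 = 0, n = 4, dt = 1)
  expect_equal(sparsity_at(0, s), 0)
  expect_equal(sparsity_at(4, s), 0.8)
  expect_equal(sparsity_at(2, s), 0.8 - 0.8 * 0.5^3) # = 0.7
  expect_error(sparsity_at(5, s), "window")
  expect_error(sparsity_at(-1, s), "window")

  set.seed(104)
  for (rep in 1:20) {
    p_i <- runif(1, 0, 0.3); p_f <- runif(1, p_i + 0.05, 0.99)
    sc <- prune_schedule(p_f = p_f, p_i = p_i, t0 = sample(0:50, 1),
                         n = sample(2:30, 1), dt = sample(1:5, 1))
    ts <- sc$t0 + (0:sc$n) * sc$dt
    ps <- vapply(ts, sparsity_at, 0, sched = sc)
    expect_true(all(diff(ps) >= -1e-12))
    expect_equal(ps[1], p_i, tolerance = 1e-12)
    expect_equal(ps[length(ps)], p_f, tolerance = 1e-12)
  }
})

test_that("regrowth conserves the nonzero count and ranks correctly", {
  cfg <- regrow_config(0)
  m <- c(1, 0.5, 0, 0.2)
  expect_identical(regrow(m, rnorm(4), cfg)$mask, m)

  # two-stage example: weakest active removed, largest-gradient inactive back
  res <- regrow(c(0.9, 0.05, 0, 0), grads = c(0, 0, 2.0, 0.1),
                regrow_config(0.5))
  expect_equal(res$removed, 2L)
  expect_equal(res$activated, 3L)
  expect_equal(res$mask, c(0.9, 0, 1e-3, 0))

  set.seed(105)
  for (r in c(0.1, 0.3)) {
    for (rep in 1:20) {
      n <- sample(10:200, 1)
      mask <- rnorm(n) * rbinom(n, 1, 0.7)
      before <- sum(mask != 0)
      out <- regrow(mask, rnorm(n), regrow_config(r), seed = rep)
      expect_identical(sum(out$mask != 0), before)
    }
  }
  # random strategy also conserves
  out <- regrow(c(1, 2, 0, 0, 3), rnorm(5), regrow_config(0.4, "random"), seed = 1)
  expect_identical(sum(out$mask != 0), 3L)
})

test_that("masking a feature dimension makes the output invariant to it", {
  set.seed(106)
  ns <- asNamespace("gplnd")
  H0 <- matrix(rnorm(4 * 5), 4, 5)
  m_x <- c(1, 0, 1, 1, 1) # dimension 2 pruned
  gm <- new_gnn_model(5, hidden = 4, L = 2, seed = 1)
  P <- aggregation_matrix(4, rbind(c(1, 2), c(3, 4)))
  out1 <- ns$gnn_forward(gm, H0, P, m_x = m_x)$prob
  H0b <- H0; H0b[, 2] <- rnorm(4)
  out2 <- ns$gnn_forward(gm, H0b, P, m_x = m_x)$prob
  expect_identical(out1, out2)
})

test_that("cgp_step follows the schedule and reaches exact final sparsity", {
  set.seed(107)
  n_w <- 100L; n_a <- 30L; n_x <- 8L
  state <- new_prune_state(n_w, n_a, n_x)
  scheds <- list(
    w = prune_schedule(p_f = 0.5, t0 = 10, n = 5, dt = 4),
    a = prune_schedule(p_f = 0.4, t0 = 10, n = 5, dt = 4),
    x = prune_schedule(p_f = 0.25, t0 = 10, n = 5, dt = 4)
  )
  rcfg <- regrow_config(0.1)
  weights <- rnorm(n_w)
  state$m_a <- runif(n_a, 0.5, 1.5)
  state$m_x <- runif(n_x, 0.5, 1.5)

  # before the window nothing changes
  s0 <- cgp_step(state, weights, list(w = rnorm(n_w), a = rnorm(n_a), x = rnorm(n_x)),
                 scheds, rcfg, t = 5)
  expect_identical(s0$m_w, state$m_w)

  traj <- NULL
  for (t in 0:30) {
    state <- cgp_step(state, weights,
                      list(w = rnorm(n_w), a = rnorm(n_a), x = rnorm(n_x)),
                      scheds, rcfg, t, seed = t)
    if (t >= 10 && t <= 30 && (t - 10) %% 4 == 0) {
      traj <- rbind(traj, c(
        t = t,
        w = sum(state$m_w != 0), a = sum(state$m_a != 0), x = sum(state$m_x != 0)
      ))
    }
  }
  # trajectory equals the schedule evaluated independently
  for (k in seq_len(nrow(traj))) {
    t <- traj[k, "t"]
    frac <- (t - 10) / 20
    p_w <- 0.5 - 0.5 * (1 - frac)^3
    expect_equal(unname(traj[k, "w"]),
                 n_w - as.integer(ceiling(p_w * n_w - 1e-9)))
    p_a <- 0.4 - 0.4 * (1 - frac)^3
    expect_equal(unname(traj[k, "a"]),
                 n_a - as.integer(ceiling(p_a * n_a - 1e-9)))
  }
  # endpoint sparsities exact by count
  expect_identical(sum(state$m_w != 0), count_retained(n_w, 0.5))
  expect_identical(sum(state$m_a != 0), count_retained(n_a, 0.4))
  expect_identical(sum(state$m_x != 0), count_retained(n_x, 0.25))

  rep <- prune_report(state)
  expect_equal(rep$retained, c(50L, 18L, 6L))
})
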