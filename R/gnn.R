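# ---- spec-level operations --------------------------------------------------

#' Mean aggregation over a node's neighborhood including itself
#'
#' `(h_i + sum_j h_j) / (|N(i)| + 1)`; an isolated node returns its own
#' vector.
#'
#' @param h_self node feature vector.
#' @param neighbor_features matrix with one neighbor per row (possibly zero
#'   rows).
#' @return Aggregated vector.
#' @export
mean_aggregate <- function(h_self, neighbor_features) {
  nf <- if (is.null(neighbor_features)) {
    matrix(0, 0L, length(h_self))
  } else {
    matrix(neighbor_features, ncol = length(h_self))
  }
  (h_self + colSums(nf)) / (nrow(nf) + 1)
}

#' Threshold-based edge selection
#'
#' Retains exactly the edges whose significance exceeds the threshold; with
#' non-decreasing thresholds the retained sets are nested.
#'
#' @param edges two-column matrix of node pairs.
#' @param scores significance per edge (here: the magnitude of the edge
#'   soft-mask).
#' @param tau threshold.
#' @return The retained subset of `edges` (same column structure).
#' @export
select_edges <- function(edges, scores, tau) {
  edges <- matrix(edges, ncol = 2L)
  stopifnot(length(scores) == nrow(edges))
  edges[scores > tau, , drop = FALSE]
}

#' Graph-level readout
#'
#' @param H final node representation matrix.
#' @param type `"mean"` (default), `"sum"`, or `"attention"` (softmax-weighted
#'   mean with scores `H w`).
#' @param w_att attention score vector (required for `"attention"`).
#' @return Graph representation vector.
#' @export
readout <- function(H, type = c("mean", "sum", "attention"), w_att = NULL) {
  type <- match.arg(type)
  H <- as.matrix(H)
  if (nrow(H) == 0L) stop("readout of an empty graph")
  switch(type,
    mean = colMeans(H),
    sum = colSums(H),
    attention = {
      stopifnot(!is.null(w_att))
      s <- as.vector(H %*% w_att)
      beta <- as.vector(softmax_rows(matrix(s, 1L)))
      as.vector(t(H) %*% beta)
    }
  )
}

#' Class probabilities from the MLP head
#'
#' @param h_G graph representation.
#' @param head list with `W1`, `b1`, `W2`, `b2` (two-layer perceptron,
#'   LeakyReLU hidden activation, softmax output). Class 1 (second column) is
#'   metastatic.
#' @param slope LeakyReLU slope.
#' @return List with `logits` and `prob` (sums to 1).
#' @export
mlp_predict <- function(h_G, head, slope = 0.01) {
  hid <- leaky_relu(head$W1 %*% h_G + head$b1, slope)
  logits <- as.vector(head$W2 %*% hid + head$b2)
  list(logits = logits, prob = as.vector(softmax_rows(matrix(logits, 1L))))
}

#' Classification loss with the pruning regularizer
#'
#' `L = -sum_c y_c log(yhat_c) + lambda * mean(|m_a|, |m_x|)`; the
#' probability is clamped at `1e-12`.
#'
#' @param prob predicted class probabilities.
#' @param label_onehot one-hot true label.
#' @param prune_state `NULL` or a `prune_state` contributing the soft masks.
#' @param lambda trade-off weight (`>= 0`).
#' @return List with `total`, `classification`, `cgp`.
#' @export
total_loss <- function(prob, label_onehot, prune_state = NULL, lambda = 0) {
  stopifnot(lambda >= 0, abs(sum(label_onehot) - 1) < 1e-9)
  lc <- -sum(label_onehot * log(pmax(prob, 1e-12)))
  lcgp <- if (is.null(prune_state)) 0 else {
    mean(c(abs(prune_state$m_a), abs(prune_state$m_x)))
  }
  list(total = lc + lambda * lcgp, classification = lc, cgp = lcgp)
}

# ---- model ------------------------------------------------------------------

#' Graph neural network tile classifier
#'
#' `L` message-passing layers with mean aggregation over the pruned edge set
#' (neighbor messages weighted by the edge soft-mask), LeakyReLU activations,
#' a mean readout and a two-layer MLP head with softmax output.
#'
#' @param d_in input node feature dimension.
#' @param hidden layer width (all layers).
#' @param L number of message-passing layers.
#' @param slope LeakyReLU slope.
#' @param seed seed for initialization.
#' @return Object of class `gnn_model`.
#' @export
new_gnn_model <- function(d_in, hidden = 64L, L = 3L, slope = 0.01, seed = 1L) {
  with_seed(derive_seed(seed, "gnn-init"), {
    params <- list()
    din <- d_in
    for (l in seq_len(L)) {
      params[[paste0("W", l)]] <- init_mat(hidden, din, fan_in = din)
      din <- hidden
    }
    params$Wh <- init_mat(hidden, din, fan_in = din)
    params$bh <- rep(0, hidden)
    params$Wo <- init_mat(2L, hidden, fan_in = hidden)
    params$bo <- rep(0, 2L)
    structure(list(params = params, d_in = d_in, hidden = hidden, L = L,
                   slope = slope),
              class = "gnn_model")
  })
}

#' One GNN message-passing layer
#'
#' `h_i^(l) = LeakyReLU(W^(l) . mean_aggregate(...))`, vectorized as
#' `LeakyReLU(P H W')` where `P` is the row-normalized (self-inclusive)
#' aggregation matrix.
#'
#' @param H node representation matrix.
#' @param P aggregation matrix (see [aggregation_matrix()]).
#' @param W layer weight matrix (`d_out x d_in`).
#' @param slope LeakyReLU slope.
#' @return Updated node representations.
#' @export
gnn_layer <- function(H, P, W, slope = 0.01) {
  leaky_relu(P %*% H %*% t(W), slope)
}

#' Aggregation matrix of the (masked) mean aggregator
#'
#' Row i equals `(e_i + sum_{j in N(i)} m_ij e_j) / (|N(i)| + 1)`: the plain
#' self-inclusive mean when all mask values are 1, and a soft-masked mean
#' under pruning.
#'
#' @param n number of nodes.
#' @param edges two-column matrix of (undirected) node pairs.
#' @param weights edge weights (soft-mask values), recycled to `nrow(edges)`.
#' @return `n x n` aggregation matrix; attribute `"deg"` holds `|N(i)| + 1`.
#' @export
aggregation_matrix <- function(n, edges, weights = 1) {
  A <- matrix(0, n, n)
  edges <- matrix(edges, ncol = 2L)
  if (nrow(edges)) {
    w <- rep_len(weights, nrow(edges))
    A[edges] <- w
    A[edges[, 2:1, drop = FALSE]] <- w
  }
  deg <- rowSums(A != 0) + 1
  P <- A / deg
  diag(P) <- diag(P) + 1 / deg
  attr(P, "deg") <- deg
  P
}

# Forward pass with caches for one tile graph.
gnn_forward <- function(model, H0, P, m_x = NULL) {
  params <- model$params
  H0m <- if (is.null(m_x)) H0 else sweep(H0, 2L, m_x, `*`)
  Hs <- list(H0m)
  Ss <- list()
  H <- H0m
  for (l in seq_len(model$L)) {
    S <- P %*% H %*% t(params[[paste0("W", l)]])
    H <- leaky_relu(S, model$slope)
    Ss[[l]] <- S
    Hs[[l + 1L]] <- H
  }
  hG <- colMeans(H)
  sh <- params$Wh %*% hG + params$bh
  hid <- leaky_relu(sh, model$slope)
  logits <- as.vector(params$Wo %*% hid + params$bo)
  prob <- as.vector(softmax_rows(matrix(logits, 1L)))
  list(Hs = Hs, Ss = Ss, hG = hG, sh = sh, hid = hid,
       logits = logits, prob = prob, H0 = H0, H0m = H0m, P = P, m_x = m_x)
}

# Cross-entropy loss and analytic gradients for one tile.
gnn_loss_grad <- function(model, fwd, label_onehot, prune_state = NULL, lambda = 0) {
  params <- model$params
  slope <- model$slope
  lt <- total_loss(fwd$prob, label_onehot, prune_state, lambda)

  grads <- list()
  dlogits <- fwd$prob - label_onehot
  grads$Wo <- outer(dlogits, as.vector(fwd$hid))
  grads$bo <- dlogits
  dhid <- as.vector(t(params$Wo) %*% dlogits)
  dsh <- dhid * as.vector(leaky_relu_grad(fwd$sh, slope))
  grads$Wh <- outer(dsh, as.vector(fwd$hG))
  grads$bh <- dsh
  dhG <- as.vector(t(params$Wh) %*% dsh)

  n <- nrow(fwd$Hs[[1L]])
  dH <- matrix(dhG, n, length(dhG), byrow = TRUE) / n
  dP <- matrix(0, n, n)
  for (l in rev(seq_len(model$L))) {
    dS <- dH * leaky_relu_grad(fwd$Ss[[l]], slope)
    Hin <- fwd$Hs[[l]]
    PH <- fwd$P %*% Hin
    grads[[paste0("W", l)]] <- t(dS) %*% PH
    dPH <- dS %*% params[[paste0("W", l)]]
    dP <- dP + dPH %*% t(Hin)
    dH <- t(fwd$P) %*% dPH
  }
  dH0m <- dH
  dm_x <- if (is.null(fwd$m_x)) NULL else colSums(dH0m * fwd$H0)
  grads <- grads[c(paste0("W", seq_len(model$L)), "Wh", "bh", "Wo", "bo")]
  list(loss = lt, grads = grads, dP = dP, dm_x = dm_x)
}

# ---- trainer ----------------------------------------------------------------

#' Train the GNN tile classifier
#'
#' Adam (Table-style defaults beta1 0.9, beta2 0.999, eps 1e-8) with cosine
#' decay, mini-batches, early stopping on a validation split, and optional
#' comprehensive gradual pruning of weights, edges (shared seed-pair index
#' space) and input feature dimensions.
#'
#' @param dataset list per tile: `H0` (node features), `edges` (two-column
#'   node-pair matrix), `pidx` (shared edge-candidate index per edge),
#'   `label` (0/1).
#' @param d_in input feature dimension.
#' @param epochs,lr,batch_size optimization settings.
#' @param hidden,L architecture.
#' @param lambda weight of the mask-sparsity regularizer.
#' @param patience early-stopping patience (epochs).
#' @param val_fraction validation fraction.
#' @param cgp `NULL` or a [cgp_config()].
#' @param n_edge_cand size of the shared edge-candidate space.
#' @param seed master seed.
#' @return List of class `gnn_fit`: `model`, `prune_state`, `history`.
#' @export
train_classifier <- function(dataset, d_in, epochs = 20L, lr = 1e-2,
                             batch_size = 8L, hidden = 64L, L = 3L,
                             lambda = 1e-3, patience = Inf, val_fraction = 0.15,
                             cgp = NULL, n_edge_cand = NULL, seed = 1L) {
  if (!length(dataset)) stop("empty dataset")
  model <- new_gnn_model(d_in, hidden = hidden, L = L, seed = seed)
  theta <- flatten_params(model$params)
  template <- model$params
  opt <- adam_init(length(theta))

  n <- length(dataset)
  n_val <- if (n >= 8) max(1L, round(val_fraction * n)) else 0L
  val_idx <- if (n_val > 0) with_seed(derive_seed(seed, "valsplit"), sample(n, n_val)) else integer(0)
  train_idx <- setdiff(seq_len(n), val_idx)
  steps_per_epoch <- max(1L, ceiling(length(train_idx) / batch_size))
  total_steps <- epochs * steps_per_epoch

  use_cgp <- !is.null(cgp)
  state <- NULL; scheds <- NULL; rcfg <- NULL; opt_a <- NULL; opt_x <- NULL
  if (use_cgp) {
    stopifnot(inherits(cgp, "cgp_config"), !is.null(n_edge_cand))
    state <- new_prune_state(length(theta), n_edge_cand, d_in)
    scheds <- make_cgp_schedules(cgp, total_steps)
    rcfg <- regrow_config(cgp$r, cgp$strategy)
    opt_a <- adam_init(n_edge_cand)
    opt_x <- adam_init(d_in)
  }

  tile_P <- function(i) {
    d <- dataset[[i]]
    w <- if (use_cgp && length(d$pidx)) state$m_a[d$pidx] else 1
    aggregation_matrix(nrow(d$H0), d$edges, w)
  }

  tile_loss_grad <- function(i, mdl) {
    d <- dataset[[i]]
    fwd <- gnn_forward(mdl, d$H0, tile_P(i), m_x = if (use_cgp) state$m_x else NULL)
    y <- if (d$label == 1L) c(0, 1) else c(1, 0)
    res <- gnn_loss_grad(mdl, fwd, y, state, if (use_cgp) lambda else 0)
    res$fwd <- fwd
    res
  }

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_acc = numeric(0))
  best <- list(loss = Inf, theta = theta, state = state)
  bad_epochs <- 0L
  t <- 0L
  n_mask <- if (use_cgp) length(state$m_a) + length(state$m_x) else 1L

  for (epoch in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, paste0("cls-epoch", epoch)), sample(train_idx))
    ep_loss <- 0
    for (b in seq_len(steps_per_epoch)) {
      batch <- ord[((b - 1L) * batch_size + 1L):min(b * batch_size, length(ord))]
      batch <- batch[!is.na(batch)]
      if (!length(batch)) next
      t <- t + 1L
      mdl <- model; mdl$params <- unflatten_params(theta, template)
      gacc <- numeric(length(theta))
      ga <- if (use_cgp) numeric(length(state$m_a)) else NULL
      gx <- if (use_cgp) numeric(d_in) else NULL
      bl <- 0
      for (i in batch) {
        res <- tile_loss_grad(i, mdl)
        gacc <- gacc + flatten_params(res$grads)
        bl <- bl + res$loss$total
        if (use_cgp) {
          d <- dataset[[i]]
          if (length(d$pidx)) {
            deg <- attr(res$fwd$P, "deg")
            dP <- res$dP
            contrib <- dP[d$edges] / deg[d$edges[, 1L]] +
              dP[d$edges[, 2:1, drop = FALSE]] / deg[d$edges[, 2L]]
            add <- rowsum(contrib, d$pidx)
            ga[as.integer(rownames(add))] <- ga[as.integer(rownames(add))] + add[, 1L]
          }
          gx <- gx + res$dm_x
        }
      }
      nb <- length(batch)
      gacc <- gacc / nb
      ep_loss <- ep_loss + bl / nb
      lr_t <- cosine_lr(lr, t, total_steps)
      if (use_cgp) gacc <- gacc * (state$m_w != 0)
      up <- adam_update(opt, theta, gacc, lr_t)
      opt <- up$opt; theta <- up$theta
      if (use_cgp) {
        # task gradient + L1 shrinkage from the lambda * mean|m| regularizer
        ga <- ga / nb + lambda * sign(state$m_a) / n_mask
        gx <- gx / nb + lambda * sign(state$m_x) / n_mask
        act_a <- state$m_a != 0; act_x <- state$m_x != 0
        ua <- adam_update(opt_a, state$m_a, ga * act_a, lr_t)
        opt_a <- ua$opt; state$m_a <- ua$theta * act_a
        ux <- adam_update(opt_x, state$m_x, gx * act_x, lr_t)
        opt_x <- ux$opt; state$m_x <- ux$theta * act_x
        theta <- theta * state$m_w
        if (is_prune_step(t, scheds$w)) {
          state <- cgp_step(state, theta, list(w = gacc, a = ga, x = gx),
                            scheds, rcfg, t, seed = derive_seed(seed, paste0("cgp", t)))
          reset <- attr(state, "weight_reset")
          theta <- theta * state$m_w
          if (length(reset)) theta[reset] <- 0
        }
      }
    }
    ep_loss <- ep_loss / steps_per_epoch
    vl <- NA_real_; vacc <- NA_real_
    if (length(val_idx)) {
      mdl <- model; mdl$params <- unflatten_params(theta, template)
      vls <- vapply(val_idx, function(i) {
        res <- tile_loss_grad(i, mdl)
        c(res$loss$total, as.numeric((res$fwd$prob[2L] > 0.5) == (dataset[[i]]$label == 1L)))
      }, c(0, 0))
      vl <- mean(vls[1L, ]); vacc <- mean(vls[2L, ])
      if (vl < best$loss - 1e-9) {
        best <- list(loss = vl, theta = theta, state = state)
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
      }
      if (bad_epochs > patience) break
    }
    history <- rbind(history, data.frame(epoch = epoch, train_loss = ep_loss,
                                         val_loss = vl, val_acc = vacc))
  }

  if (length(val_idx) && is.finite(best$loss) && is.finite(patience)) {
    theta <- best$theta
    state <- best$state
  }
  model$params <- unflatten_params(theta, template)
  structure(list(model = model, prune_state = state, history = history,
                 seed = seed),
            class = "gnn_fit")
}

#' Predict the metastasis probability of a tile
#'
#' @param fit a `gnn_fit`.
#' @param tile list with `H0`, `edges`, `pidx`.
#' @return List with `prob` (length 2, classes non-metastatic/metastatic) and
#'   `label` (thresholded at 0.5).
#' @export
predict_classifier <- function(fit, tile) {
  stopifnot(inherits(fit, "gnn_fit"))
  use_cgp <- !is.null(fit$prune_state)
  w <- if (use_cgp && length(tile$pidx)) fit$prune_state$m_a[tile$pidx] else 1
  P <- aggregation_matrix(nrow(tile$H0), tile$edges, w)
  fwd <- gnn_forward(fit$model, tile$H0, P,
                     m_x = if (use_cgp) fit$prune_state$m_x else NULL)
  list(prob = fwd$prob, label = as.integer(fwd$prob[2L] > 0.5))
}
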