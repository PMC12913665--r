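# ---- Adam -------------------------------------------------------------------

adam_init <- function(n) {
  list(m = numeric(n), v = numeric(n), t = 0L,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_update <- function(opt, theta, grad, lr) {
  opt$t <- opt$t + 1L
  opt$m <- opt$beta1 * opt$m + (1 - opt$beta1) * grad
  opt$v <- opt$beta2 * opt$v + (1 - opt$beta2) * grad^2
  mhat <- opt$m / (1 - opt$beta1^opt$t)
  vhat <- opt$v / (1 - opt$beta2^opt$t)
  list(opt = opt, theta = theta - lr * mhat / (sqrt(vhat) + opt$eps))
}

cosine_lr <- function(lr0, t, total) {
  lr0 * 0.5 * (1 + cos(pi * min(t, total) / total))
}

# ---- shared edge-index space ------------------------------------------------

#' Edge-candidate index of an unordered node pair
#'
#' Edge masks are shared across tiles by indexing candidate edges with the
#' unordered pair of SLIC grid-seed ids, which are stable across tiles
#' segmented with the same grid.
#'
#' @param si,sj seed ids (1-based, `si != sj`).
#' @param n_seeds size of the seed grid.
#' @return Linear index into the length `n_seeds * (n_seeds - 1) / 2`
#'   candidate list.
#' @export
edge_pair_index <- function(si, sj, n_seeds) {
  a <- pmin(si, sj); b <- pmax(si, sj)
  (a - 1L) * n_seeds - (a * (a - 1L)) %/% 2L + (b - a)
}

n_edge_candidates <- function(n_seeds) (n_seeds * (n_seeds - 1L)) %/% 2L

# Per-tile mapping of node pairs (i < j) to shared candidate indices.
tile_pair_map <- function(sp, n_seeds) {
  n <- sp$n_nodes
  if (n < 2L) return(list(ii = integer(0), jj = integer(0), pidx = integer(0)))
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  list(ii = pr[, 1L], jj = pr[, 2L],
       pidx = edge_pair_index(sp$seed_index[pr[, 1L]],
                              sp$seed_index[pr[, 2L]], n_seeds))
}

# N x N multiplicative edge-mask matrix for one tile (unit diagonal).
edge_mask_matrix <- function(m_a, pm, n) {
  M <- matrix(1, n, n)
  if (length(pm$pidx)) {
    v <- m_a[pm$pidx]
    M[cbind(pm$ii, pm$jj)] <- v
    M[cbind(pm$jj, pm$ii)] <- v
  }
  M
}

# Scatter a dense dM gradient matrix into the shared candidate space.
accumulate_edge_grad <- function(gvec, dM, pm) {
  if (length(pm$pidx)) {
    contrib <- dM[cbind(pm$ii, pm$jj)] + dM[cbind(pm$jj, pm$ii)]
    add <- rowsum(contrib, pm$pidx)
    gvec[as.integer(rownames(add))] <- gvec[as.integer(rownames(add))] + add[, 1L]
  }
  gvec
}

# ---- CGP wiring shared by both trainers ------------------------------------

make_cgp_schedules <- function(cgp, total_steps) {
  n <- cgp$n %||% 20L
  t0 <- max(1L, round((cgp$t0_frac %||% 0.1) * total_steps))
  t_end <- max(t0 + n, round((cgp$end_frac %||% 0.8) * total_steps))
  dt <- max(1L, floor((t_end - t0) / n))
  list(
    w = prune_schedule(p_f = cgp$p_f[["w"]], p_i = cgp$p_i %||% 0, t0 = t0, n = n, dt = dt),
    a = prune_schedule(p_f = cgp$p_f[["a"]], p_i = cgp$p_i %||% 0, t0 = t0, n = n, dt = dt),
    x = prune_schedule(p_f = cgp$p_f[["x"]], p_i = cgp$p_i %||% 0, t0 = t0, n = n, dt = dt)
  )
}

#' Comprehensive-pruning training configuration
#'
#' @param p_f named vector of target sparsities for `w` (weights), `a`
#'   (edges), `x` (feature dimensions); a single number is recycled.
#' @param r regrowth ratio.
#' @param strategy regrowth strategy.
#' @param lambda weight of the mask-sparsity (L1) term in the classifier
#'   loss.
#' @param t0_frac,end_frac fractions of total training steps at which gradual
#'   pruning starts and ends.
#' @param n number of pruning iterations.
#' @param p_i initial sparsity.
#' @return A list of class `cgp_config`.
#' @export
cgp_config <- function(p_f = 0.5, r = 0.1, strategy = "gradient", lambda = 1e-3,
                       t0_frac = 0.1, end_frac = 0.8, n = 20L, p_i = 0) {
  if (length(p_f) == 1L) p_f <- c(w = unname(p_f), a = unname(p_f), x = unname(p_f))
  stopifnot(all(c("w", "a", "x") %in% names(p_f)))
  structure(list(p_f = p_f, r = r, strategy = strategy, lambda = lambda,
                 t0_frac = t0_frac, end_frac = end_frac, n = n, p_i = p_i),
            class = "cgp_config")
}

# ---- segmentation trainer ---------------------------------------------------

#' Train the DGC autoencoder on tile graphs
#'
#' Adam with cosine learning-rate decay, mini-batches, optional early
#' stopping on a held-in validation split, periodic recomputation of the
#' dynamic adjacencies, and (optionally) comprehensive gradual pruning with
#' regrowth interleaved into the step loop.
#'
#' @param graphs list of tile graphs, each a list with `X` (node attributes),
#'   `A1` (initial adjacency), `sp` (superpixel map) and `gt_mask`.
#' @param epochs,lr,batch_size optimization settings.
#' @param patience early-stopping patience in epochs (on the validation
#'   loss); `Inf` disables.
#' @param val_fraction fraction of tiles held in for validation.
#' @param graph_update_every recompute dynamic adjacencies every this many
#'   epochs.
#' @param cgp `NULL` or a [cgp_config()].
#' @param model optional pre-built [new_dgc_model()].
#' @param seed master seed (weight init, batching, regrowth).
#' @param n_seeds SLIC seed-grid size shared by all tiles (defaults to the
#'   first tile's).
#' @return List of class `dgc_fit`: `model`, `prune_state`, `history`
#'   (per-epoch train/val loss), `n_seeds`.
#' @export
train_segmenter <- function(graphs, epochs = 20L, lr = 1e-2, batch_size = 8L,
                            patience = Inf, val_fraction = 0.15,
                            graph_update_every = 5L, cgp = NULL, model = NULL,
                            seed = 1L, n_seeds = NULL) {
  stopifnot(length(graphs) >= 1L)
  C <- ncol(graphs[[1L]]$X)
  n_seeds <- n_seeds %||% graphs[[1L]]$sp$n_seeds
  if (is.null(model)) model <- new_dgc_model(C, seed = seed)

  prep <- lapply(graphs, function(g) {
    lab <- as.vector(g$sp$labels) + 1L
    sizes <- tabulate(lab, nbins = g$sp$n_nodes)
    gpix <- as.vector(rowsum(as.vector(g$gt_mask) * 1, lab))
    list(g_nodes = pool_mask_majority(g$gt_mask, g$sp), sizes = sizes,
         gpix = gpix, pm = tile_pair_map(g$sp, n_seeds))
  })

  n <- length(graphs)
  n_val <- if (n >= 8) max(1L, round(val_fraction * n)) else 0L
  val_idx <- if (n_val > 0) {
    with_seed(derive_seed(seed, "valsplit"), sample(n, n_val))
  } else {
    integer(0)
  }
  train_idx <- setdiff(seq_len(n), val_idx)

  theta <- flatten_params(model$params)
  template <- model$params
  opt <- adam_init(length(theta))
  steps_per_epoch <- max(1L, ceiling(length(train_idx) / batch_size))
  total_steps <- epochs * steps_per_epoch

  use_cgp <- !is.null(cgp)
  state <- NULL; scheds <- NULL; rcfg <- NULL
  opt_a <- NULL; opt_x <- NULL
  if (use_cgp) {
    stopifnot(inherits(cgp, "cgp_config"))
    state <- new_prune_state(length(theta), n_edge_candidates(n_seeds), C)
    scheds <- make_cgp_schedules(cgp, total_steps)
    rcfg <- regrow_config(cgp$r, cgp$strategy)
    opt_a <- adam_init(length(state$m_a))
    opt_x <- adam_init(length(state$m_x))
  }

  adj_cache <- vector("list", n)
  refresh_adjacencies <- function() {
    mdl <- model; mdl$params <- unflatten_params(theta, template)
    for (i in seq_len(n)) {
      g <- graphs[[i]]
      m_x <- if (use_cgp) state$m_x else NULL
      M <- if (use_cgp) edge_mask_matrix(state$m_a, prep[[i]]$pm, g$sp$n_nodes) else NULL
      fwd <- dgc_forward_full(mdl, g$X, g$A1, M = M, m_x = m_x)
      adj_cache[[i]] <<- fwd$A_raw
    }
  }

  tile_loss_grad <- function(i, mdl) {
    g <- graphs[[i]]
    m_x <- if (use_cgp) state$m_x else NULL
    M <- if (use_cgp) edge_mask_matrix(state$m_a, prep[[i]]$pm, g$sp$n_nodes) else NULL
    fwd <- dgc_forward_full(mdl, g$X, g$A1, M = M, m_x = m_x,
                            adjacencies = adj_cache[[i]])
    dgc_loss_grad(mdl, fwd, prep[[i]]$g_nodes, prep[[i]]$sizes, prep[[i]]$gpix)
  }

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(loss = Inf, theta = theta, state = state)
  bad_epochs <- 0L
  t <- 0L

  for (epoch in seq_len(epochs)) {
    if ((epoch - 1L) %% graph_update_every == 0L) refresh_adjacencies()
    ord <- with_seed(derive_seed(seed, paste0("epoch", epoch)), sample(train_idx))
    ep_loss <- 0
    for (b in seq_len(steps_per_epoch)) {
      batch <- ord[((b - 1L) * batch_size + 1L):min(b * batch_size, length(ord))]
      batch <- batch[!is.na(batch)]
      if (!length(batch)) next
      t <- t + 1L
      mdl <- model; mdl$params <- unflatten_params(theta, template)
      gacc <- numeric(length(theta))
      ga <- if (use_cgp) numeric(length(state$m_a)) else NULL
      gx <- if (use_cgp) numeric(C) else NULL
      bl <- 0
      for (i in batch) {
        res <- tile_loss_grad(i, mdl)
        gacc <- gacc + flatten_params(res$grads)
        if (use_cgp) {
          ga <- accumulate_edge_grad(ga, res$dM, prep[[i]]$pm)
          gx <- gx + res$dm_x
        }
        bl <- bl + res$loss
      }
      nb <- length(batch)
      gacc <- gacc / nb
      ep_loss <- ep_loss + bl / nb
      lr_t <- cosine_lr(lr, t, total_steps)
      if (use_cgp) gacc <- gacc * (state$m_w != 0)
      up <- adam_update(opt, theta, gacc, lr_t)
      opt <- up$opt; theta <- up$theta
      if (use_cgp) {
        ga <- ga / nb; gx <- gx / nb
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
    vl <- NA_real_
    if (length(val_idx)) {
      mdl <- model; mdl$params <- unflatten_params(theta, template)
      vl <- mean(vapply(val_idx, function(i) tile_loss_grad(i, mdl)$loss, 0))
      if (vl < best$loss - 1e-9) {
        best <- list(loss = vl, theta = theta, state = state)
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
      }
      if (bad_epochs > patience) break
    }
    history <- rbind(history, data.frame(epoch = epoch, train_loss = ep_loss,
                                         val_loss = vl))
  }

  if (length(val_idx) && is.finite(best$loss) && is.finite(patience)) {
    theta <- best$theta
    state <- best$state
  }
  model$params <- unflatten_params(theta, template)
  structure(list(model = model, prune_state = state, history = history,
                 n_seeds = n_seeds, seed = seed),
            class = "dgc_fit")
}

#' Segment one tile graph with a trained model
#'
#' @param fit a `dgc_fit` from [train_segmenter()].
#' @param graph tile graph (list with `X`, `A1`, `sp`).
#' @return A `segmentation_output` (see [dgc_decode()]).
#' @export
predict_segmenter <- function(fit, graph) {
  stopifnot(inherits(fit, "dgc_fit"))
  use_cgp <- !is.null(fit$prune_state)
  m_x <- if (use_cgp) fit$prune_state$m_x else NULL
  M <- if (use_cgp) {
    pm <- tile_pair_map(graph$sp, fit$n_seeds)
    edge_mask_matrix(fit$prune_state$m_a, pm, graph$sp$n_nodes)
  } else {
    NULL
  }
  fwd <- dgc_forward_full(fit$model, graph$X, graph$A1, M = M, m_x = m_x)
  out <- list(node_logits = fwd$logits, node_prob = fwd$prob,
              node_labels = as.integer(fwd$prob > 0.5),
              pixel_mask = paint_nodes(as.integer(fwd$prob > 0.5), graph$sp),
              prob_map = paint_nodes(fwd$prob, graph$sp),
              Z = fwd$enc$Z)
  structure(out, class = "segmentation_output")
}
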