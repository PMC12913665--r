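# ---- parameter plumbing -----------------------------------------------------

flatten_params <- function(params) {
  unlist(lapply(params, as.vector), use.names = FALSE)
}

unflatten_params <- function(vec, template) {
  out <- template
  pos <- 0L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    out[[nm]] <- array(vec[pos + seq_len(n)], dim = dim(template[[nm]]) %||% n)
    if (is.null(dim(template[[nm]]))) out[[nm]] <- as.vector(out[[nm]])
    pos <- pos + n
  }
  out
}

init_mat <- function(nr, nc, fan_in = nr) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

# ---- model ------------------------------------------------------------------

#' Dynamic graph convolution autoencoder for superpixel segmentation
#'
#' Encoder: a node-attribute attention block, a first graph convolution on
#' the initial L1-affinity adjacency, and further convolutions on
#' adjacencies re-derived from the concatenation of the previous layer output
#' with the attention-enhanced attributes. Decoder: two graph convolutions on
#' the final evolved adjacency down to one logit per node; sigmoid
#' probabilities thresholded at 0.5 give node labels, painted back onto the
#' superpixels for the pixel mask.
#'
#' @param C node attribute dimension.
#' @param enc_widths widths of the encoder layers.
#' @param dec_width hidden width of the decoder.
#' @param att_hidden hidden width of the attention block.
#' @param slope LeakyReLU negative slope.
#' @param seed seed for the random initialization.
#' @return Object of class `dgc_model` holding the parameter list and the
#'   architecture record.
#' @export
new_dgc_model <- function(C, enc_widths = c(32L, 64L, 64L), dec_width = 32L,
                          att_hidden = 16L, slope = 0.01, seed = 1L) {
  with_seed(derive_seed(seed, "dgc-init"), {
    L <- length(enc_widths)
    params <- list(
      W_a = init_mat(att_hidden, C, fan_in = C),
      b_a = rep(0, att_hidden),
      H_a = init_mat(C, att_hidden, fan_in = att_hidden)
    )
    din <- C
    for (k in seq_len(L)) {
      params[[paste0("W", k)]] <- init_mat(din, enc_widths[k])
      din <- enc_widths[k]
    }
    params$V1 <- init_mat(din, dec_width)
    params$V2 <- init_mat(dec_width, 1L)
    params$b_dec <- 0
    structure(list(params = params, C = C, enc_widths = enc_widths,
                   dec_width = dec_width, att_hidden = att_hidden,
                   slope = slope, n_layers = L),
              class = "dgc_model")
  })
}

# ---- spec-level operations --------------------------------------------------

#' Node-attribute attention scores
#'
#' `u_i = H_a tanh(W_a x_i + b_a)`; `alpha_i = softmax(u_i)` (row-wise, with
#' max subtraction for stability).
#'
#' @param X `N x C` node attribute matrix.
#' @param params list with `W_a` (`h x C`), `b_a` (length h), `H_a`
#'   (`C x h`).
#' @return List with `u` (scores) and `alpha` (normalized weights, rows sum
#'   to 1).
#' @export
attention_scores <- function(X, params) {
  X <- as.matrix(X)
  Tn <- tanh(X %*% t(params$W_a) + matrix(params$b_a, nrow(X), length(params$b_a),
                                          byrow = TRUE))
  u <- Tn %*% t(params$H_a)
  list(u = u, alpha = softmax_rows(u), tanh_cache = Tn)
}

#' Attention-enhanced node attributes
#'
#' `X~_i = alpha_i (*) X_i + X_i` — elementwise modulation with a residual.
#'
#' @param X node attribute matrix.
#' @param alpha attention weights with rows summing to 1.
#' @return Enhanced attribute matrix of the same shape.
#' @export
enhance_attributes <- function(X, alpha) {
  stopifnot(all(dim(X) == dim(alpha)),
            max(abs(rowSums(alpha) - 1)) < 1e-6)
  alpha * X + X
}

#' First encoder layer
#'
#' `Y_1 = LeakyReLU(A_1 X~ W_1)`.
#'
#' @param A1 initial normalized adjacency.
#' @param Xt enhanced attribute matrix.
#' @param W1 weight matrix.
#' @param slope LeakyReLU negative slope.
#' @return Node feature matrix.
#' @export
encode_first_layer <- function(A1, Xt, W1, slope = 0.01) {
  leaky_relu(A1 %*% Xt %*% W1, slope)
}

#' Evolved adjacency from concatenated features
#'
#' Concatenates the previous layer output with the enhanced attributes
#' channel-wise, rebuilds the L1 affinity and renormalizes.
#'
#' @param Y_prev previous layer node features.
#' @param Xt enhanced attribute matrix (same row count).
#' @return Normalized adjacency; the concatenation is attached as attribute
#'   `"Ytilde"`.
#' @export
evolve_topology <- function(Y_prev, Xt) {
  stopifnot(nrow(Y_prev) == nrow(Xt))
  Yt <- cbind(Y_prev, Xt)
  A <- normalize_adjacency(build_affinity(Yt))
  attr(A, "Ytilde") <- Yt
  A
}

#' Run the dynamic graph convolution encoder
#'
#' Applies the first layer on `A1`, then alternates topology evolution and
#' graph convolution. The dynamic adjacencies are treated as data (detached
#' from the gradient); `adjacencies` can supply frozen ones, matching the
#' periodic graph-update schedule used in training.
#'
#' @param Xt enhanced (and possibly feature-masked) attribute matrix.
#' @param A1 initial adjacency.
#' @param model a `dgc_model` (or a bare parameter list plus `n_layers`).
#' @param M optional symmetric edge-mask matrix (unit diagonal) applied
#'   elementwise to every adjacency.
#' @param adjacencies optional list of precomputed evolved adjacencies for
#'   layers `2..L`.
#' @return Encoder state: list with `Y` (per-layer outputs), `A` (effective
#'   per-layer adjacencies), `S` (pre-activations), and `Z = Y[[L]]`.
#' @export
dgc_encode <- function(Xt, A1, model, M = NULL, adjacencies = NULL) {
  params <- model$params
  L <- model$n_layers
  slope <- model$slope
  mask <- function(A) if (is.null(M)) A else A * M
  Y <- S <- A <- A_raw <- vector("list", L)
  A_raw[[1L]] <- A1
  A[[1L]] <- mask(A1)
  S[[1L]] <- A[[1L]] %*% Xt %*% params$W1
  Y[[1L]] <- leaky_relu(S[[1L]], slope)
  for (k in seq_len(L)[-1L]) {
    Ak <- if (!is.null(adjacencies)) adjacencies[[k]] else evolve_topology(Y[[k - 1L]], Xt)
    attr(Ak, "Ytilde") <- NULL
    A_raw[[k]] <- Ak
    A[[k]] <- mask(Ak)
    S[[k]] <- A[[k]] %*% Y[[k - 1L]] %*% params[[paste0("W", k)]]
    Y[[k]] <- leaky_relu(S[[k]], slope)
  }
  list(Y = Y, S = S, A = A, A_raw = A_raw, Z = Y[[L]])
}

#' Decode node probabilities and paint the pixel mask
#'
#' Two graph convolutions on the final adjacency map the encoder output to
#' one logit per node; probabilities are painted constant within each
#' superpixel.
#'
#' @param enc_state result of [dgc_encode()].
#' @param model the `dgc_model`.
#' @param sp optional superpixel map; when given, the pixel mask and painted
#'   probability map are included.
#' @param threshold node-label threshold on the probabilities.
#' @return List of class `segmentation_output`: `node_logits`, `node_prob`,
#'   `node_labels`, and (with `sp`) `pixel_mask`, `prob_map`.
#' @export
dgc_decode <- function(enc_state, model, sp = NULL, threshold = 0.5) {
  params <- model$params
  A <- enc_state$A[[length(enc_state$A)]]
  Sd1 <- A %*% enc_state$Z %*% params$V1
  Yd1 <- leaky_relu(Sd1, model$slope)
  logits <- as.vector(A %*% Yd1 %*% params$V2 + params$b_dec)
  prob <- sigmoid(logits)
  out <- list(node_logits = logits, node_prob = prob,
              node_labels = as.integer(prob > threshold))
  if (!is.null(sp)) {
    out$pixel_mask <- paint_nodes(out$node_labels, sp)
    out$prob_map <- paint_nodes(prob, sp)
  }
  structure(out, class = "segmentation_output")
}

#' Paint per-node values onto the pixel grid
#'
#' @param values one value per node.
#' @param sp superpixel map.
#' @return `H x W` matrix, constant within each superpixel.
#' @export
paint_nodes <- function(values, sp) {
  stopifnot(length(values) == sp$n_nodes)
  matrix(values[as.vector(sp$labels) + 1L], nrow(sp$labels), ncol(sp$labels))
}

#' Majority-pool a binary pixel mask to superpixel labels
#'
#' @param mask binary `H x W` matrix.
#' @param sp superpixel map.
#' @return Integer vector of node labels (1 where more than half the pixels
#'   are positive).
#' @export
pool_mask_majority <- function(mask, sp) {
  stopifnot(all(dim(mask) == dim(sp$labels)))
  lab <- as.vector(sp$labels) + 1L
  frac <- as.vector(rowsum(as.vector(mask) * 1, lab)) /
    tabulate(lab, nbins = sp$n_nodes)
  as.integer(frac > 0.5)
}

#' Segmentation loss: binary cross-entropy plus soft-Dice
#'
#' The BCE term compares node probabilities with the majority-pooled ground
#' truth; the Dice term is computed on pixel counts (probabilities painted
#' constant per superpixel), with an additive smoothing constant of one pixel
#' so that empty-mask tiles are well-defined.
#'
#' @param pred a `segmentation_output` (or list with `node_prob`).
#' @param gt_mask binary ground-truth pixel mask.
#' @param sp superpixel map used for pooling.
#' @param eps probability clamp for the BCE log.
#' @return List with `total`, `bce`, `dice` (the soft-Dice score) and
#'   `dice_term = 1 - dice`.
#' @export
segmentation_loss <- function(pred, gt_mask, sp, eps = 1e-7) {
  if (!all(gt_mask %in% c(0, 1))) stop("ground-truth mask must be binary")
  p <- pred$node_prob
  g <- pool_mask_majority(gt_mask, sp)
  sizes <- tabulate(as.vector(sp$labels) + 1L, nbins = sp$n_nodes)
  pc <- pmin(pmax(p, eps), 1 - eps)
  bce <- -mean(g * log(pc) + (1 - g) * log(1 - pc))
  gpix <- as.vector(rowsum(as.vector(gt_mask) * 1, as.vector(sp$labels) + 1L))
  inter <- sum(sizes * p * (gpix / sizes))
  dice <- (2 * sum(p * gpix) + 1) / (sum(sizes * p) + sum(gpix) + 1)
  list(total = bce + (1 - dice), bce = bce, dice = dice, dice_term = 1 - dice)
}

# ---- full forward/backward for training ------------------------------------

# Forward pass with caches. gt pooling is done by the caller. Returns
# everything needed for the analytic backward sweep.
dgc_forward_full <- function(model, X, A1, M = NULL, m_x = NULL, adjacencies = NULL) {
  params <- model$params
  att <- attention_scores(X, params)
  Xt <- enhance_attributes(X, att$alpha)
  Xin <- if (is.null(m_x)) Xt else sweep(Xt, 2L, m_x, `*`)
  enc <- dgc_encode(Xin, A1, model, M = M, adjacencies = adjacencies)
  A_last <- enc$A[[length(enc$A)]]
  Sd1 <- A_last %*% enc$Z %*% params$V1
  Yd1 <- leaky_relu(Sd1, model$slope)
  Pd2 <- A_last %*% Yd1
  logits <- as.vector(Pd2 %*% params$V2 + params$b_dec)
  prob <- sigmoid(logits)
  list(att = att, Xt = Xt, Xin = Xin, enc = enc,
       Sd1 = Sd1, Yd1 = Yd1, Pd2 = Pd2, logits = logits, prob = prob,
       X = X, M = M, m_x = m_x, A_raw = enc$A_raw)
}

# Loss + analytic gradients of the segmentation objective w.r.t. all model
# parameters, the feature soft-mask and the edge-mask matrix. The dynamic
# adjacencies are held fixed (detached), matching the training rule.
dgc_loss_grad <- function(model, fwd, g_nodes, sizes, gpix) {
  params <- model$params
  slope <- model$slope
  N <- length(fwd$prob)
  p <- fwd$prob

  # loss
  eps <- 1e-7
  pc <- pmin(pmax(p, eps), 1 - eps)
  bce <- -mean(g_nodes * log(pc) + (1 - g_nodes) * log(1 - pc))
  num <- 2 * sum(p * gpix) + 1
  den <- sum(sizes * p) + sum(gpix) + 1
  dice <- num / den
  loss <- bce + (1 - dice)

  # d loss / d logits
  dbce_dlogit <- (p - g_nodes) / N
  ddice_dp <- (2 * gpix * den - num * sizes) / den^2
  dlogits <- dbce_dlogit + (-ddice_dp) * p * (1 - p)

  grads <- lapply(params, function(x) array(0, dim = dim(x) %||% length(x)))
  grads$b_a <- rep(0, length(params$b_a))
  grads$b_dec <- 0
  L <- model$n_layers
  A_eff <- fwd$enc$A
  A_last <- A_eff[[L]]
  dA <- lapply(A_eff, function(a) a * 0)

  dlog_mat <- matrix(dlogits, ncol = 1L)
  grads$V2 <- t(fwd$Pd2) %*% dlog_mat
  grads$b_dec <- sum(dlogits)
  dPd2 <- dlog_mat %*% t(params$V2)
  dA[[L]] <- dA[[L]] + dPd2 %*% t(fwd$Yd1)
  dYd1 <- t(A_last) %*% dPd2
  dSd1 <- dYd1 * leaky_relu_grad(fwd$Sd1, slope)
  Pd1 <- A_last %*% fwd$enc$Z
  grads$V1 <- t(Pd1) %*% dSd1
  dPd1 <- dSd1 %*% t(params$V1)
  dA[[L]] <- dA[[L]] + dPd1 %*% t(fwd$enc$Z)
  dZ <- t(A_last) %*% dPd1

  dY <- dZ
  for (k in rev(seq_len(L))) {
    Sk <- fwd$enc$S[[k]]
    dSk <- dY * leaky_relu_grad(Sk, slope)
    inp <- if (k == 1L) fwd$Xin else fwd$enc$Y[[k - 1L]]
    Pk <- A_eff[[k]] %*% inp
    grads[[paste0("W", k)]] <- t(Pk) %*% dSk
    dPk <- dSk %*% t(params[[paste0("W", k)]])
    dA[[k]] <- dA[[k]] + dPk %*% t(inp)
    dY <- t(A_eff[[k]]) %*% dPk
  }
  dXin <- dY

  dm_x <- if (is.null(fwd$m_x)) NULL else colSums(dXin * fwd$Xt)
  dXt <- if (is.null(fwd$m_x)) dXin else sweep(dXin, 2L, fwd$m_x, `*`)

  dalpha <- dXt * fwd$X
  alpha <- fwd$att$alpha
  dU <- alpha * (dalpha - rowSums(dalpha * alpha))
  Tn <- fwd$att$tanh_cache
  grads$H_a <- t(dU) %*% Tn
  dTn <- dU %*% params$H_a
  dpre <- dTn * (1 - Tn^2)
  grads$W_a <- t(dpre) %*% fwd$X
  grads$b_a <- colSums(dpre)

  # edge-mask gradient matrix: sum over layers of dA_eff * raw adjacency
  dM <- NULL
  if (!is.null(fwd$M)) {
    dM <- Reduce(`+`, lapply(seq_len(L), function(k) dA[[k]] * fwd$A_raw[[k]]))
  }
  list(loss = loss, bce = bce, dice = dice, grads = grads,
       dM = dM, dm_x = dm_x, dlogits = dlogits)
}
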