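#' SLIC superpixel segmentation
#'
#' Localized k-means in joint (color, position) space, seeded on a regular
#' grid, as used to turn a tile into graph nodes. Colors are scaled to a
#' 0-100 range so the `compactness` parameter has its conventional meaning;
#' each pixel is only compared against seeds within a 2S window (S = grid
#' step). A final connectivity pass merges stray fragments into an adjacent
#' superpixel. Cluster identity is preserved: node i carries the index of the
#' grid seed it descends from, which gives a stable cross-tile indexing of
#' node pairs.
#'
#' @param img image array (values in `[0, 1]`).
#' @param n_segments requested number of superpixels (>= 1); the realized
#'   count `n_nodes` may differ slightly.
#' @param compactness trade-off between color similarity and spatial
#'   proximity; larger values give squarer superpixels.
#' @param n_iter number of assignment/update sweeps.
#' @return A list of class `superpixel_map`: `labels` (H x W integer matrix
#'   with values `0 .. n_nodes-1`), `n_nodes`, `seed_index` (length
#'   `n_nodes`, original grid-seed id of each node), `centers`
#'   (`n_nodes x 2` centroids), `n_seeds` (size of the initial grid).
#' @export
segment_superpixels <- function(img, n_segments = 200, compactness = 10, n_iter = 10) {
  img <- as_image(img)
  h <- dim(img)[1L]; w <- dim(img)[2L]; nc <- dim(img)[3L]
  if (n_segments < 1) stop("n_segments must be >= 1")
  if (n_segments > h * w) stop("n_segments exceeds the pixel count")
  if (n_segments == 1) {
    labels <- matrix(0L, h, w)
    return(structure(list(
      labels = labels, n_nodes = 1L, seed_index = 1L,
      centers = matrix(c((h + 1) / 2, (w + 1) / 2), 1L),
      n_seeds = 1L
    ), class = "superpixel_map"))
  }

  gy <- max(1L, round(sqrt(n_segments * h / w)))
  gx <- max(1L, ceiling(n_segments / gy))
  k <- gy * gx
  step <- sqrt(h * w / k)
  cy <- (seq_len(gy) - 0.5) * h / gy
  cx <- (seq_len(gx) - 0.5) * w / gx
  centers <- cbind(rep(cy, times = gx), rep(cx, each = gy))

  colmat <- matrix(img, h * w, nc) * 100 # pseudo-Lab scaling
  ccol <- matrix(0, k, nc)
  pr <- rep(seq_len(h), times = w)
  pc <- rep(seq_len(w), each = h)
  for (j in seq_len(k)) {
    px <- round(pmin(pmax(centers[j, 1L], 1), h))
    qx <- round(pmin(pmax(centers[j, 2L], 1), w))
    ccol[j, ] <- colmat[(qx - 1L) * h + px, ]
  }

  label <- integer(h * w)
  m2s2 <- (compactness / step)^2
  win <- ceiling(2 * step)
  for (it in seq_len(n_iter)) {
    best <- rep(Inf, h * w)
    for (j in seq_len(k)) {
      ys <- max(1L, floor(centers[j, 1L] - win)):min(h, ceiling(centers[j, 1L] + win))
      xs <- max(1L, floor(centers[j, 2L] - win)):min(w, ceiling(centers[j, 2L] + win))
      idx <- as.vector(outer(ys, (xs - 1L) * h, `+`))
      dc2 <- rowSums((colmat[idx, , drop = FALSE] -
                        matrix(ccol[j, ], length(idx), nc, byrow = TRUE))^2)
      ds2 <- (pr[idx] - centers[j, 1L])^2 + (pc[idx] - centers[j, 2L])^2
      d <- dc2 + m2s2 * ds2
      upd <- d < best[idx]
      if (any(upd)) {
        ii <- idx[upd]
        best[ii] <- d[upd]
        label[ii] <- j
      }
    }
    # any pixel outside every window: assign to nearest center spatially
    miss <- which(label == 0L)
    if (length(miss)) {
      for (i in miss) {
        dd <- (pr[i] - centers[, 1L])^2 + (pc[i] - centers[, 2L])^2
        label[i] <- which.min(dd)
      }
    }
    for (j in seq_len(k)) {
      sel <- label == j
      if (any(sel)) {
        centers[j, ] <- c(mean(pr[sel]), mean(pc[sel]))
        ccol[j, ] <- colMeans(colmat[sel, , drop = FALSE])
      }
    }
  }

  lab_mat <- matrix(label, h, w)
  lab_mat <- enforce_connectivity(lab_mat, min_size = max(4L, floor(step^2 / 4)))

  kept <- sort(unique(as.vector(lab_mat)))
  relab <- match(as.vector(lab_mat), kept) - 1L
  labels <- matrix(as.integer(relab), h, w)
  n_nodes <- length(kept)
  centers_out <- matrix(0, n_nodes, 2L)
  for (j in seq_len(n_nodes)) {
    sel <- relab == (j - 1L)
    centers_out[j, ] <- c(mean(pr[sel]), mean(pc[sel]))
  }
  structure(list(
    labels = labels, n_nodes = n_nodes, seed_index = as.integer(kept),
    centers = centers_out, n_seeds = k
  ), class = "superpixel_map")
}

# 4-connected component labeling (column-major flood fill).
label_components <- function(lab_mat) {
  h <- nrow(lab_mat); w <- ncol(lab_mat)
  comp <- matrix(0L, h, w)
  comp_label <- integer(0)
  ncomp <- 0L
  stack <- integer(h * w)
  for (start in seq_len(h * w)) {
    if (comp[start] != 0L) next
    ncomp <- ncomp + 1L
    lab <- lab_mat[start]
    comp_label[ncomp] <- lab
    top <- 1L
    stack[1L] <- start
    comp[start] <- ncomp
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      r <- ((p - 1L) %% h) + 1L
      cc <- ((p - 1L) %/% h) + 1L
      for (q in c(if (r > 1L) p - 1L, if (r < h) p + 1L,
                  if (cc > 1L) p - h, if (cc < w) p + h)) {
        if (comp[q] == 0L && lab_mat[q] == lab) {
          comp[q] <- ncomp
          top <- top + 1L
          stack[top] <- q
        }
      }
    }
  }
  list(comp = comp, label = comp_label, n = ncomp,
       sizes = tabulate(as.vector(comp), nbins = ncomp))
}

# Merge connected components smaller than min_size into an adjacent kept
# region and make every label's pixel set 4-connected. Iterates because an
# absorption can strand fragments created by earlier merges.
enforce_connectivity <- function(lab_mat, min_size) {
  h <- nrow(lab_mat); w <- ncol(lab_mat)
  out <- lab_mat
  for (round in seq_len(20L)) {
    cl <- label_components(out)
    # the main (largest) component of each label, if big enough, is "good"
    good <- logical(cl$n)
    seen <- integer(max(out))
    for (cid in order(cl$sizes, decreasing = TRUE)) {
      l <- cl$label[cid]
      if (seen[l] == 0L && cl$sizes[cid] >= min_size) {
        seen[l] <- cid
        good[cid] <- TRUE
      }
    }
    if (!any(good)) { # degenerate: keep the single largest component
      good[which.max(cl$sizes)] <- TRUE
    }
    bad <- which(!good)
    if (!length(bad)) break
    changed <- FALSE
    for (cid in bad) {
      cells <- which(cl$comp == cid)
      r <- ((cells - 1L) %% h) + 1L
      cc <- ((cells - 1L) %/% h) + 1L
      nb <- c(cells[r > 1L] - 1L, cells[r < h] + 1L,
              cells[cc > 1L] - h, cells[cc < w] + h)
      nb <- nb[good[cl$comp[nb]]]
      if (!length(nb)) next # not adjacent to a kept region yet; next round
      tt <- table(out[nb])
      out[cells] <- as.integer(names(tt)[which.max(tt)])
      changed <- TRUE
    }
    if (!changed) break
  }
  out
}

#' Average-pool a per-pixel feature map over superpixels
#'
#' @param feature_map `H x W x C` array (or `H x W` matrix) of per-pixel
#'   feature vectors whose spatial shape matches `sp$labels`.
#' @param sp a [segment_superpixels()] result.
#' @return `n_nodes x C` node attribute matrix; row i is the mean feature
#'   vector over superpixel i.
#' @export
pool_node_features <- function(feature_map, sp) {
  stopifnot(inherits(sp, "superpixel_map"))
  feature_map <- as_image(feature_map)
  if (!all(dim(feature_map)[1:2] == dim(sp$labels))) {
    stop("feature map shape does not match the superpixel label map")
  }
  nc <- dim(feature_map)[3L]
  fm <- matrix(feature_map, ncol = nc)
  lab <- as.vector(sp$labels) + 1L
  sums <- rowsum(fm, lab)
  counts <- tabulate(lab, nbins = sp$n_nodes)
  X <- sums / counts
  dimnames(X) <- NULL
  X
}

#' L1-distance affinity between node attributes
#'
#' `phi_ij = exp(-||X_i - X_j||_1)`, giving values in `(0, 1]` with an exact
#' unit diagonal.
#'
#' @param X node attribute matrix (rows = nodes).
#' @return Symmetric affinity matrix.
#' @export
build_affinity <- function(X) {
  X <- as.matrix(X)
  stopifnot(all(is.finite(X)))
  D <- as.matrix(stats::dist(X, method = "manhattan"))
  dimnames(D) <- NULL
  exp(-D)
}

#' Symmetric degree normalization of an affinity matrix
#'
#' `A = D^(-1/2) Phi D^(-1/2)` with `D_ii = sum_j Phi_ij`.
#'
#' @param Phi symmetric nonnegative affinity matrix with positive row sums.
#' @return Normalized adjacency matrix.
#' @export
normalize_adjacency <- function(Phi) {
  Phi <- as.matrix(Phi)
  d <- rowSums(Phi)
  stopifnot(all(d > 0))
  s <- 1 / sqrt(d)
  Phi * outer(s, s)
}

#' Keep only each node's strongest affinities
#'
#' Optional sparsifier for large graphs: zeroes all but the K largest
#' off-diagonal entries per row, then re-symmetrizes by the elementwise
#' maximum. The diagonal is kept.
#'
#' @param Phi affinity matrix.
#' @param K neighbors kept per node.
#' @return Sparsified affinity matrix.
#' @export
knn_sparsify <- function(Phi, K) {
  n <- nrow(Phi)
  stopifnot(K >= 1, K <= n - 1)
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    off <- Phi[i, ]
    off[i] <- -Inf
    keep[i, order(off, decreasing = TRUE)[seq_len(K)]] <- TRUE
  }
  keep <- keep | t(keep)
  diag(keep) <- TRUE
  out <- Phi
  out[!keep] <- 0
  out
}

#' Fixed convolutional feature encoder
#'
#' A small 2-D convolutional network with seeded random (He-initialized)
#' filters and LeakyReLU activations, used as a deterministic per-pixel
#' feature extractor. The raw color channels are passed through alongside the
#' learnedless conv features; each output channel is z-scored over the tile
#' and scaled by `1/C` so that pairwise L1 distances between pooled node
#' attributes fall in a range where `exp(-d)` affinities stay responsive.
#'
#' @param in_channels input channel count.
#' @param widths output widths of the three conv layers; the encoder output
#'   has `in_channels + widths[length(widths)]` channels.
#' @param kernel odd conv kernel size.
#' @param seed seed for the random filters.
#' @param affinity_scale target scale of typical pairwise L1 distances
#'   between pooled node attributes; larger values contrast the `exp(-d)`
#'   affinities more (4 keeps same-region affinities high while pushing
#'   dissimilar-region affinities toward 0).
#' @return Object of class `conv_encoder`.
#' @export
conv_encoder <- function(in_channels = 3L, widths = c(8L, 16L, 29L),
                         kernel = 3L, seed = 1L, affinity_scale = 4) {
  stopifnot(kernel %% 2 == 1)
  with_seed(derive_seed(seed, "conv-encoder"), {
    filters <- list()
    ci <- in_channels
    for (l in seq_along(widths)) {
      fan_in <- kernel^2 * ci
      filters[[l]] <- matrix(stats::rnorm(fan_in * widths[l], 0, sqrt(2 / fan_in)),
                             fan_in, widths[l])
      ci <- widths[l]
    }
    structure(list(filters = filters, kernel = kernel, in_channels = in_channels,
                   widths = widths, seed = seed, affinity_scale = affinity_scale),
              class = "conv_encoder")
  })
}

# Unfold all channels of an H x W x C array into (H*W) x (k^2 * C).
im2col <- function(x, k) {
  nc <- dim(x)[3L]
  do.call(cbind, lapply(seq_len(nc), function(c) neighborhood_matrix(x[, , c], k)))
}

#' @rdname conv_encoder
#' @param img image array with `in_channels` channels.
#' @param enc a `conv_encoder`.
#' @return `encode_features` returns an `H x W x C` feature array.
#' @export
encode_features <- function(img, enc) {
  stopifnot(inherits(enc, "conv_encoder"))
  img <- as_image(img)
  h <- dim(img)[1L]; w <- dim(img)[2L]
  x <- img
  for (l in seq_along(enc$filters)) {
    z <- im2col(x, enc$kernel) %*% enc$filters[[l]]
    z <- leaky_relu(z)
    x <- array(z, dim = c(h, w, ncol(z)))
  }
  out <- array(0, dim = c(h, w, dim(img)[3L] + dim(x)[3L]))
  out[, , seq_len(dim(img)[3L])] <- img
  out[, , dim(img)[3L] + seq_len(dim(x)[3L])] <- x
  nc <- dim(out)[3L]
  gain <- (enc$affinity_scale %||% 4) / nc
  for (c in seq_len(nc)) {
    ch <- out[, , c]
    mu <- mean(ch)
    sdv <- sqrt(mean((ch - mu)^2))
    out[, , c] <- if (sdv > 1e-8) (ch - mu) / sdv * gain else 0
  }
  out
}

#' Per-superpixel shape, intensity, texture and boundary descriptors
#'
#' Twelve descriptors per node: mean R/G/B, mean and sd of gray intensity,
#' contrast of the node vs the tile mean, four texture statistics (gray
#' variance, mean absolute horizontal/vertical gradient, intensity range),
#' relative area, and perimeter/area ratio.
#'
#' @param img image array in `[0, 1]`.
#' @param sp superpixel map.
#' @return `n_nodes x 12` matrix.
#' @export
superpixel_descriptors <- function(img, sp) {
  img <- as_image(img)
  h <- dim(img)[1L]; w <- dim(img)[2L]
  gray <- (img[, , 1L] + img[, , min(2L, dim(img)[3L])] +
             img[, , min(3L, dim(img)[3L])]) / 3
  lab <- as.vector(sp$labels) + 1L
  n <- sp$n_nodes
  counts <- tabulate(lab, nbins = n)

  rgb <- matrix(img, ncol = dim(img)[3L])
  mean_rgb <- rowsum(rgb, lab) / counts
  if (ncol(mean_rgb) < 3L) mean_rgb <- cbind(mean_rgb, mean_rgb, mean_rgb)[, 1:3]
  g <- as.vector(gray)
  mean_g <- as.vector(rowsum(g, lab)) / counts
  var_g <- as.vector(rowsum(g^2, lab)) / counts - mean_g^2
  sd_g <- sqrt(pmax(var_g, 0))
  contrast <- mean_g - mean(g)

  gx <- cbind(abs(gray[, -1] - gray[, -w]), 0)
  gy <- rbind(abs(gray[-1, ] - gray[-h, ]), 0)
  grad_x <- as.vector(rowsum(as.vector(gx), lab)) / counts
  grad_y <- as.vector(rowsum(as.vector(gy), lab)) / counts
  rng <- vapply(seq_len(n), function(j) {
    v <- g[lab == j]
    max(v) - min(v)
  }, 0)

  # boundary pixels: label differs from a 4-neighbor (image border excluded)
  L <- sp$labels
  bnd <- matrix(FALSE, h, w)
  bnd[-h, ] <- bnd[-h, ] | (L[-h, ] != L[-1, ])
  bnd[-1, ] <- bnd[-1, ] | (L[-1, ] != L[-h, ])
  bnd[, -w] <- bnd[, -w] | (L[, -w] != L[, -1])
  bnd[, -1] <- bnd[, -1] | (L[, -1] != L[, -w])
  perim <- as.vector(rowsum(as.vector(bnd) * 1, lab))
  cbind(mean_rgb[, 1:3], mean_g, sd_g, contrast,
        var_g, grad_x, grad_y, rng,
        counts / (h * w), perim / counts)
}

#' Serialize a tile graph to JSON node-link format
#'
#' @param X node attribute matrix.
#' @param A adjacency matrix.
#' @param sp superpixel map (optional, adds centroids and seed indices).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_graph_json <- function(X, A, path, sp = NULL) {
  n <- nrow(X)
  edges <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  obj <- list(
    nodes = lapply(seq_len(n), function(i) {
      nd <- list(id = i - 1L, features = unname(X[i, ]))
      if (!is.null(sp)) {
        nd$center <- unname(sp$centers[i, ])
        nd$seed_index <- sp$seed_index[i]
      }
      nd
    }),
    links = lapply(seq_len(nrow(edges)), function(e) {
      list(source = edges[e, 1L] - 1L, target = edges[e, 2L] - 1L,
           weight = A[edges[e, 1L], edges[e, 2L]])
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
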