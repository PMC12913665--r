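#' Pipeline configuration
#'
#' Defaults are the reference training configuration (Adam, learning rate 1e-4, batch
#' size 8, 120 epochs, early-stopping patience 15, cosine decay, graph update
#' every 5 epochs, HLLE neighborhood 12 and output dimension 64); scaled-down
#' runs override `n_tiles`, `epochs_*` and `lr_*`. A `cgp` entry (see
#' [cgp_config()]) switches on joint pruning of the classifier.
#'
#' @param n_tiles number of synthetic tiles.
#' @param n_train tiles used for training (the rest are held out).
#' @param pos_fraction fraction of metastatic tiles.
#' @param tile_size tile side length.
#' @param n_segments,compactness SLIC settings.
#' @param knn_edges neighbors kept per node in the classifier edge set.
#' @param epochs_seg,epochs_cls training epochs of the two models.
#' @param lr_seg,lr_cls learning rates.
#' @param batch_size,patience,val_fraction,graph_update_every optimization
#'   settings shared by both trainers.
#' @param hlle_k,hlle_d embedding neighborhood size and dimension.
#' @param lambda sparsity-regularizer weight in the classifier loss.
#' @param cgp `NULL` or a [cgp_config()] applied to the classifier.
#' @param cgp_seg `NULL` or a [cgp_config()] applied to the segmenter.
#' @param augment augment training tiles (rotation, flips, scalings).
#' @param filter_k denoising kernel size.
#' @param seed master seed.
#' @param out_dir optional output directory for artifacts.
#' @param params generator parameters ([tile_params()]).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_tiles = 300L, n_train = 200L,
                            pos_fraction = 0.315, tile_size = 64L,
                            n_segments = 64L, compactness = 10,
                            knn_edges = 8L,
                            epochs_seg = 120L, epochs_cls = 120L,
                            lr_seg = 1e-4, lr_cls = 1e-4,
                            batch_size = 8L, patience = 15L,
                            val_fraction = 0.15, graph_update_every = 5L,
                            hlle_k = 12L, hlle_d = 64L, lambda = 1e-3,
                            cgp = NULL, cgp_seg = NULL, augment = FALSE,
                            filter_k = 3L, seed = 1L, out_dir = NULL,
                            params = NULL) {
  if (is.null(params)) params <- tile_params(size = tile_size)
  stopifnot(n_train < n_tiles)
  structure(as.list(environment()), class = "pipeline_config")
}

# Build the graph representation of one (already denoised) tile.
build_tile_graph <- function(proc, gt_mask, enc, cfg) {
  sp <- segment_superpixels(proc, cfg$n_segments, cfg$compactness)
  fm <- encode_features(normalize_image(proc), enc)
  X <- pool_node_features(fm, sp)
  Phi <- build_affinity(X)
  A1 <- normalize_adjacency(Phi)
  desc <- superpixel_descriptors(proc, sp)
  Phi_knn <- knn_sparsify(Phi, min(cfg$knn_edges, sp$n_nodes - 1L))
  e <- which(upper.tri(Phi_knn) & Phi_knn > 0, arr.ind = TRUE)
  pidx <- edge_pair_index(sp$seed_index[e[, 1L]], sp$seed_index[e[, 2L]],
                          sp$n_seeds)
  list(X = X, A1 = A1, sp = sp, gt_mask = gt_mask, desc = desc,
       edges = unname(e), pidx = pidx)
}

# Per-tile descriptor vector pooled from the segmentation output, the input
# of the across-tile manifold embedding.
tile_descriptor <- function(seg, graph) {
  p <- seg$node_prob
  Z <- seg$Z
  wp <- if (sum(p) > 1e-12) p / sum(p) else rep(1 / length(p), length(p))
  c(mean(p), max(p), mean(p > 0.5), stats::sd(p),
    colMeans(Z), as.vector(t(Z) %*% wp))
}

#' Run the full detection pipeline on synthetic tiles
#'
#' synth -> preprocess -> graph construction -> DGC segmentation -> HLLE
#' embedding of pooled segmentation descriptors -> GNN classification ->
#' evaluation. Deterministic given the configuration: re-running with the
#' same config reproduces the metrics exactly.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return List of class `pipeline_result`: `metrics` (held-out
#'   [compute_metrics()] record), `predictions` (data frame), `seg_fit`,
#'   `cls_fit`, `embedding`, `split`, `config`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), quiet = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t_start <- Sys.time()

  say("stage synth: %d tiles", cfg$n_tiles)
  data <- generate_dataset(cfg$n_tiles, cfg$pos_fraction, cfg$seed, cfg$params)
  labels <- data$manifest$label

  split <- with_seed(derive_seed(cfg$seed, "split"),
                     sample(cfg$n_tiles, cfg$n_train))
  test_idx <- setdiff(seq_len(cfg$n_tiles), split)

  say("stage preprocess")
  proc <- lapply(data$tiles, function(t) denoise(t$image, k = cfg$filter_k, "gaussian"))

  enc <- conv_encoder(seed = cfg$seed)
  say("stage graph: SLIC + features")
  graphs <- lapply(seq_len(cfg$n_tiles), function(i) {
    build_tile_graph(proc[[i]], data$tiles[[i]]$mask, enc, cfg)
  })

  train_graphs <- graphs[split]
  if (isTRUE(cfg$augment)) {
    aug <- list()
    for (i in split) {
      imgs <- augment(proc[[i]])
      msks <- augment(array(data$tiles[[i]]$mask, dim = c(dim(data$tiles[[i]]$mask), 1L)),
                      interp = "nearest")
      for (v in seq_along(imgs)) {
        m <- (msks[[v]][, , 1L] > 0.5) * 1L
        if (!all(dim(imgs[[v]])[1:2] == dim(proc[[i]])[1:2])) next # keep graph sizes uniform
        aug[[length(aug) + 1L]] <- build_tile_graph(imgs[[v]], m, enc, cfg)
      }
    }
    train_graphs <- c(train_graphs, aug)
  }

  say("stage segment: training DGC autoencoder")
  seg_fit <- train_segmenter(
    train_graphs, epochs = cfg$epochs_seg, lr = cfg$lr_seg,
    batch_size = cfg$batch_size, patience = cfg$patience,
    val_fraction = cfg$val_fraction, graph_update_every = cfg$graph_update_every,
    cgp = cfg$cgp_seg, seed = cfg$seed
  )
  segs <- lapply(graphs, function(g) predict_segmenter(seg_fit, g))

  say("stage embed: HLLE over %d tile descriptors", cfg$n_tiles)
  D <- t(vapply(seq_len(cfg$n_tiles), function(i) tile_descriptor(segs[[i]], graphs[[i]]),
                numeric(4L + 2L * ncol(segs[[1L]]$Z))))
  emb <- hlle_transform(D, k = cfg$hlle_k, d = cfg$hlle_d)

  say("stage classify: GNN with %s", if (is.null(cfg$cgp)) "no pruning" else "CGP")
  d_in <- ncol(graphs[[1L]]$desc) + 1L + ncol(emb$Y)
  H0_all <- lapply(seq_len(cfg$n_tiles), function(i) {
    n <- graphs[[i]]$sp$n_nodes
    cbind(graphs[[i]]$desc, segs[[i]]$node_prob,
          matrix(emb$Y[i, ], n, ncol(emb$Y), byrow = TRUE))
  })
  train_rows <- do.call(rbind, H0_all[split])
  mu <- colMeans(train_rows)
  sdv <- pmax(apply(train_rows, 2L, stats::sd), 1e-8)
  dataset <- lapply(seq_len(cfg$n_tiles), function(i) {
    list(H0 = sweep(sweep(H0_all[[i]], 2L, mu), 2L, sdv, `/`),
         edges = graphs[[i]]$edges, pidx = graphs[[i]]$pidx,
         label = labels[i])
  })
  cls_fit <- train_classifier(
    dataset[split], d_in = d_in, epochs = cfg$epochs_cls, lr = cfg$lr_cls,
    batch_size = cfg$batch_size, lambda = cfg$lambda, patience = cfg$patience,
    val_fraction = cfg$val_fraction, cgp = cfg$cgp,
    n_edge_cand = n_edge_candidates(graphs[[1L]]$sp$n_seeds), seed = cfg$seed
  )

  say("stage evaluate")
  preds <- lapply(seq_len(cfg$n_tiles), function(i) predict_classifier(cls_fit, dataset[[i]]))
  pred_df <- data.frame(
    tile_id = data$manifest$tile_id,
    p_metastatic = vapply(preds, function(p) p$prob[2L], 0),
    pred_label = vapply(preds, function(p) p$label, 1L),
    label = labels,
    test = seq_len(cfg$n_tiles) %in% test_idx
  )
  metrics <- compute_metrics(
    pred_df$pred_label[test_idx], labels[test_idx],
    pred_masks = lapply(segs[test_idx], function(s) s$pixel_mask),
    gt_masks = lapply(data$tiles[test_idx], function(t) t$mask)
  )

  res <- structure(list(
    metrics = metrics, predictions = pred_df, seg_fit = seg_fit,
    cls_fit = cls_fit, embedding = emb, split = list(train = split, test = test_idx),
    config = cfg, segs = segs, graphs = graphs, tiles = data$tiles,
    dataset = dataset,
    runtime_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  ), class = "pipeline_result")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(metrics), file.path(cfg$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(pred_df, file.path(cfg$out_dir, "predictions.csv"),
                     row.names = FALSE)
    cfg_out <- cfg
    cfg_out$params <- unclass(cfg_out$params)
    cfg_out$cgp <- if (is.null(cfg$cgp)) NULL else unclass(cfg$cgp)
    cfg_out$cgp_seg <- if (is.null(cfg$cgp_seg)) NULL else unclass(cfg$cgp_seg)
    yaml::write_yaml(cfg_out, file.path(cfg$out_dir, "config.yaml"))
  }
  res
}

#' Retrain only the classifier of a finished pipeline run
#'
#' Reuses the synthetic data, graphs, segmentation and embedding of an
#' existing [run_pipeline()] result and retrains the GNN classifier (for
#' example with a different pruning configuration or seed), returning the
#' held-out metrics of the new classifier. This is how pruned and dense
#' classifiers are compared under identical upstream features.
#'
#' @param res a `pipeline_result`.
#' @param cgp `NULL` or a [cgp_config()].
#' @param seed seed for the retrained classifier.
#' @return List with `metrics`, `cls_fit`, `predictions`.
#' @export
retrain_classifier <- function(res, cgp = NULL, seed = NULL) {
  stopifnot(inherits(res, "pipeline_result"))
  cfg <- res$config
  seed <- seed %||% cfg$seed
  d_in <- ncol(res$dataset[[1L]]$H0)
  cls_fit <- train_classifier(
    res$dataset[res$split$train], d_in = d_in, epochs = cfg$epochs_cls,
    lr = cfg$lr_cls, batch_size = cfg$batch_size, lambda = cfg$lambda,
    patience = cfg$patience, val_fraction = cfg$val_fraction, cgp = cgp,
    n_edge_cand = n_edge_candidates(res$graphs[[1L]]$sp$n_seeds), seed = seed
  )
  test_idx <- res$split$test
  preds <- lapply(test_idx, function(i) predict_classifier(cls_fit, res$dataset[[i]]))
  labels <- vapply(res$tiles[test_idx], function(t) t$label, 1L)
  pred_label <- vapply(preds, function(p) p$label, 1L)
  list(
    metrics = compute_metrics(pred_label, labels),
    cls_fit = cls_fit,
    predictions = data.frame(tile = test_idx, pred = pred_label, label = labels)
  )
}
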