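# gplnd

Graph-based detection of lymph node metastases in histology tiles, for
computational-pathology researchers who want a compact, fully reproducible
implementation of a superpixel-graph segmentation + pruning + manifold
embedding + graph classification pipeline that runs on a laptop with no
external data.

## What it implements

Tiles are partitioned into SLIC superpixels; each superpixel becomes a graph
node with average-pooled encoder features, and edges carry L1-affinity
weights with symmetric degree normalization:

    phi_ij = exp(-||X_i - X_j||_1),   A_1 = D^{-1/2} Phi D^{-1/2}.

On this graph the package provides:

* **Segmentation** — a dynamic graph convolution (DGC) autoencoder with
  node-attribute attention `X~_i = softmax(H_a tanh(W_a X_i + b_a)) (*) X_i
  + X_i`; deeper layers rebuild the adjacency from `[Y_{k-1} || X~]` so the
  topology evolves with the features. Trained with binary cross-entropy plus
  soft-Dice on majority-pooled superpixel labels.
* **Comprehensive gradual pruning (CGP)** — joint magnitude pruning of model
  weights (binary mask, global TopK), graph edges and input feature
  dimensions (trainable soft masks) on the cubic schedule
  `p_t = p_f + (p_i - p_f) (1 - (t - t_0)/(n*dt))^3`, with gradient-based
  regrowth that conserves nonzero counts exactly
  (`N - ceil(p*N)` survivors after a prune at rate `p`).
* **HLLE** — Hessian-weighted locally linear embedding: local-PCA tangent
  coordinates, quadratic-fit Hessians, simplex-constrained reconstruction
  weights (`sum w = 1, w >= 0`, solved with quadprog), and the bottom
  eigenvectors of `(I - W)'(I - W)`.
* **GNN classification** — mean-aggregation message passing over the pruned
  edge set, mean readout, MLP head, cross-entropy plus an L1 mask-sparsity
  regularizer `L = L_classification + lambda * L_CGP`.
* **Synthetic data** — a seeded generator of H&E-like 64x64 tiles (pink
  textured stroma, dark nuclei, irregular metastatic blobs, per-tile stain
  shift, pixel noise) with pixel-exact masks, so every stage is testable
  offline.
* **Evaluation** — accuracy/precision/recall/F1 from tile labels; Dice, IoU,
  area-fraction MAE and symmetric Hausdorff distance from masks.

All neural components are plain matrix code with hand-derived analytic
gradients, verified against finite differences in the test suite.

## Worked example

```r
library(gplnd)

# one synthetic metastatic tile and its graph
tile <- generate_tile(seed = 7, tile_params(), label = 1)
sp <- segment_superpixels(tile$image, n_segments = 64, compactness = 10)
cat("tile:", dim(tile$image)[1], "x", dim(tile$image)[2],
    "| mask fraction:", round(mean(tile$mask), 3),
    "| superpixels:", sp$n_nodes, "\n")

# scaled-down end-to-end run: 300 tiles, 200 train / 100 test, 20 epochs
cfg <- pipeline_config(n_tiles = 300, n_train = 200,
                       epochs_seg = 20, epochs_cls = 20,
                       lr_seg = 1e-2, lr_cls = 1e-2, patience = Inf, seed = 1)
res <- run_pipeline(cfg)
m <- res$metrics
cat(sprintf("held-out accuracy %.3f | precision %.3f | recall %.3f | F1 %.3f\n",
            m$accuracy, m$precision, m$recall, m$f1))
cat(sprintf("segmentation IoU %.3f | Dice %.3f | MAE %.4f | Hausdorff %.1f px\n",
            m$iou, m$dsc, m$mae, m$hd))

# pruning arithmetic and a 50%-sparsity classifier
cat("retained at 50%:", count_retained(1967616, 0.5), "\n")
pruned <- retrain_classifier(res, cgp = cgp_config(0.5), seed = 1)
cat(sprintf("dense accuracy %.2f -> 50%%-pruned accuracy %.2f\n",
            m$accuracy, pruned$metrics$accuracy))
```

Output (about a minute on one CPU):

```
tile: 64 x 64 | mask fraction: 0.199 | superpixels: 58
held-out accuracy 0.970 | precision 0.914 | recall 1.000 | F1 0.955
segmentation IoU 0.899 | Dice 0.947 | MAE 0.0029 | Hausdorff 7.6 px
retained at 50%: 983808
dense accuracy 0.97 -> 50%-pruned accuracy 0.99
```

The first line describes one generated tile: a fifth of its area is
metastatic blob, split over 58 superpixels. The pipeline then classifies
held-out tiles (97% correct, every metastatic tile found) and overlaps the
true blob mask at IoU 0.90; the MAE line says predicted and true tumor area
fractions differ by 0.3% of the tile on average. The last lines show the
pruning arithmetic on a 1,967,616-parameter budget and that halving the
classifier's weights, edges and feature dimensions does not cost held-out
accuracy on this task.

The per-tile masks live in `res$segs[[i]]$pixel_mask`, tile probabilities in
`res$predictions`, and `vignettes/methods.Rmd` documents every model and
default.

A thin CLI covering the same stages ships in `inst/cli/gpln.R`:

```sh
Rscript inst/cli/gpln.R synth --n 300 --pos-fraction 0.315 --seed 7 --out tiles/
Rscript inst/cli/gpln.R run --seed 1 --tiles 300 --train 200 --epochs 20 --out run/
Rscript inst/cli/gpln.R embed --in features.csv --k 12 --dim 64 --out embedding.csv
```

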