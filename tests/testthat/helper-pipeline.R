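# Shared desk-scale pipeline runs, memoized so the end-to-end checks and the
# generator guards reuse the same computation.
.pipeline_cache <- new.env(parent = emptyenv())

desk_config <- function(seed) {
  pipeline_config(
    n_tiles = 300L, n_train = 200L, pos_fraction = 0.315,
    epochs_seg = 20L, epochs_cls = 20L, lr_seg = 1e-2, lr_cls = 1e-2,
    patience = Inf, seed = seed
  )
}

desk_run <- function(seed) {
  key <- paste0("run", seed)
  if (is.null(.pipeline_cache[[key]])) {
    .pipeline_cache[[key]] <- run_pipeline(desk_config(seed))
  }
  .pipeline_cache[[key]]
}

rank_auc <- function(score, y) {
  r <- rank(score)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
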