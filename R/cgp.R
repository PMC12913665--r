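#' Indices of the K smallest-magnitude values
#'
#' Tie-breaks go to the lowest index, so pruning is deterministic.
#'
#' @param values numeric vector.
#' @param K how many indices to return, `0 <= K <= length(values)`.
#' @return Integer vector of K (1-based) indices, in increasing magnitude
#'   order.
#' @export
topk_smallest <- function(values, K) {
  n <- length(values)
  if (K < 0 || K > n) stop("K out of range")
  if (K == 0) return(integer(0))
  order(abs(values), seq_len(n))[seq_len(K)]
}

# ceiling() guarded against floating error in p * N (e.g. 0.07 * 300).
ceil_count <- function(x) as.integer(ceiling(x - 1e-9))

#' Retained count after pruning at rate p
#'
#' `N - ceiling(p * N)` candidates survive a prune at sparsity `p`.
#'
#' @param N number of candidates.
#' @param p sparsity in `[0, 1]`.
#' @return Integer retained count.
#' @export
count_retained <- function(N, p) {
  stopifnot(N >= 0, p >= 0, p <= 1)
  as.integer(N - ceil_count(p * N))
}

#' Gradual pruning schedule
#'
#' Cubic interpolation from the initial sparsity `p_i` at step `t0` to the
#' target `p_f` at step `t0 + n * dt`:
#' `p_t = p_f + (p_i - p_f) * (1 - (t - t0)/(n * dt))^3`.
#'
#' @param p_i initial sparsity.
#' @param p_f target sparsity.
#' @param t0 first pruning step.
#' @param n number of pruning iterations.
#' @param dt interval between pruning steps.
#' @return A list of class `prune_schedule`.
#' @export
prune_schedule <- function(p_f, p_i = 0, t0 = 0L, n = 20L, dt = 1L) {
  stopifnot(p_i >= 0, p_i < 1, p_f >= 0, p_f < 1, n >= 1, dt >= 1)
  structure(list(p_i = p_i, p_f = p_f, t0 = t0, n = n, dt = dt),
            class = "prune_schedule")
}

#' @rdname prune_schedule
#' @param t training step; must lie in `[t0, t0 + n * dt]`.
#' @param sched a `prune_schedule`.
#' @return `sparsity_at` returns the scheduled sparsity at step `t`.
#' @export
sparsity_at <- function(t, sched) {
  stopifnot(inherits(sched, "prune_schedule"))
  t_end <- sched$t0 + sched$n * sched$dt
  if (t < sched$t0 || t > t_end) stop("t outside the pruning window")
  frac <- (t - sched$t0) / (sched$n * sched$dt)
  sched$p_f + (sched$p_i - sched$p_f) * (1 - frac)^3
}

is_prune_step <- function(t, sched) {
  t >= sched$t0 && t <= sched$t0 + sched$n * sched$dt &&
    (t - sched$t0) %% sched$dt == 0
}

#' Joint prune state over weights, edges and feature dimensions
#'
#' Holds the binary weight mask `m_w`, the real-valued edge soft-mask `m_a`,
#' the real-valued feature soft-mask `m_x` (both initialized at 1 and trained
#' as differentiable attention-like masks), and the current sparsities.
#'
#' @param n_w,n_a,n_x candidate counts for weights, edges, feature dims.
#' @return A list of class `prune_state`.
#' @export
new_prune_state <- function(n_w, n_a, n_x) {
  structure(list(
    m_w = rep(1, n_w), m_a = rep(1, n_a), m_x = rep(1, n_x),
    p_w = 0, p_a = 0, p_x = 0
  ), class = "prune_state")
}

# Shared prune kernel: zero the ceil(p * N) smallest-|score| candidates and
# return a fresh mask with exactly N - ceil(p * N) nonzeros.
prune_by_magnitude <- function(scores, p) {
  stopifnot(p >= 0, p < 1)
  n <- length(scores)
  idx <- topk_smallest(scores, ceil_count(p * n))
  mask <- rep(1, n)
  mask[idx] <- 0
  list(mask = mask, idx = idx)
}

#' Global magnitude pruning of model weights
#'
#' Zeroes the `ceil(p_w * N)` smallest effective weight magnitudes across all
#' layers jointly, recording the result in a binary mask.
#'
#' @param w flattened numeric vector of all model weights.
#' @param m_w current binary mask (same length).
#' @param p_w sparsity in `[0, 1)`.
#' @return List with `m_w` (updated mask), `w` (masked weights), `idx`
#'   (pruned indices), `n_retained`.
#' @export
prune_weights <- function(w, m_w = rep(1, length(w)), p_w = 0) {
  stopifnot(length(m_w) == length(w))
  pr <- prune_by_magnitude(abs(w * m_w), p_w)
  list(m_w = pr$mask, w = pr$mask * w, idx = pr$idx,
       n_retained = as.integer(sum(pr$mask != 0)))
}

#' Prune the edge soft-mask
#'
#' @param m_a edge soft-mask over the candidate edge list.
#' @param p_a sparsity in `[0, 1)`.
#' @return List with `m_a` (mask values, pruned entries zeroed), `idx`,
#'   `n_retained`.
#' @export
prune_edges <- function(m_a, p_a) {
  pr <- prune_by_magnitude(abs(m_a), p_a)
  list(m_a = pr$mask * m_a, idx = pr$idx,
       n_retained = as.integer(sum(pr$mask != 0)))
}

#' Prune the feature-dimension soft-mask
#'
#' Applied at the input layer only; no hidden-channel pruning.
#'
#' @param m_x feature soft-mask of length `d`.
#' @param p_x sparsity in `[0, 1)`.
#' @param d expected number of feature dimensions.
#' @return List with `m_x`, `idx`, `n_retained`.
#' @export
prune_features <- function(m_x, p_x, d = length(m_x)) {
  if (length(m_x) != d) stop("length(m_x) != d")
  pr <- prune_by_magnitude(abs(m_x), p_x)
  list(m_x = pr$mask * m_x, idx = pr$idx,
       n_retained = as.integer(sum(pr$mask != 0)))
}

#' Regrowth configuration
#'
#' @param r regrowth ratio in `[0, 1)`: the fraction of active entries
#'   removed and re-activated at each regrowth event.
#' @param strategy `"gradient"`, `"momentum"` (both rank eliminated
#'   candidates by `|g|`) or `"random"`.
#' @param eps_regrow value given to re-activated soft-mask entries; regrown
#'   weights restart at 0.
#' @return A list of class `regrow_config`.
#' @export
regrow_config <- function(r = 0.1, strategy = c("gradient", "momentum", "random"),
                          eps_regrow = 1e-3) {
  strategy <- match.arg(strategy)
  stopifnot(r >= 0, r < 1)
  structure(list(r = r, strategy = strategy, eps_regrow = eps_regrow),
            class = "regrow_config")
}

#' Remove-and-regrow step on one mask
#'
#' Removes the `floor(r * n_active)` active entries of smallest magnitude,
#' then re-activates the same number of inactive candidates — those with the
#' largest gradient magnitude (or at random). The nonzero count is invariant.
#'
#' @param mask numeric mask vector (0 = inactive).
#' @param grads gradient (or momentum) magnitudes for all candidates.
#' @param cfg a [regrow_config()].
#' @param scores magnitudes used to pick removals; defaults to `abs(mask)`
#'   (soft masks). For binary weight masks pass `abs(w)`.
#' @param new_value value assigned to re-activated entries
#'   (`cfg$eps_regrow` for masks, 0 for weights).
#' @param seed seed for the `"random"` strategy.
#' @return List with `mask`, `removed`, `activated` index vectors.
#' @export
regrow <- function(mask, grads, cfg, scores = abs(mask),
                   new_value = cfg$eps_regrow, seed = 1L) {
  stopifnot(inherits(cfg, "regrow_config"), length(grads) == length(mask))
  active <- which(mask != 0)
  k <- floor(cfg$r * length(active))
  if (k < 1) return(list(mask = mask, removed = integer(0), activated = integer(0)))
  removed <- active[topk_smallest(scores[active], k)]
  mask[removed] <- 0
  inactive <- which(mask == 0)
  activated <- if (cfg$strategy == "random") {
    with_seed(derive_seed(seed, "regrow"), sample(inactive, k))
  } else {
    g <- abs(grads[inactive])
    inactive[order(-g, seq_along(inactive))[seq_len(k)]]
  }
  mask[activated] <- new_value
  list(mask = mask, removed = removed, activated = activated)
}

#' One comprehensive-pruning step
#'
#' At steps `t` inside the pruning window with `t = t0 (mod dt)`, prunes
#' weights, edges and feature dimensions at the scheduled sparsity and then
#' regrows each element; at other steps it is a no-op. The caller performs
#' the forward/backward pass and supplies current weights and gradients.
#'
#' @param state a [new_prune_state()].
#' @param weights flattened model weight vector (length `n_w`).
#' @param grads list with numeric vectors `w`, `a`, `x`: gradient magnitudes
#'   for the three candidate sets.
#' @param scheds list of three [prune_schedule()]s named `w`, `a`, `x`.
#' @param cfg a [regrow_config()].
#' @param t current training step.
#' @param seed seed for random regrowth.
#' @return Updated `prune_state`; attribute `"weight_reset"` carries indices
#'   of weights that must restart at 0 after regrowth.
#' @export
cgp_step <- function(state, weights, grads, scheds, cfg, t, seed = 1L) {
  stopifnot(inherits(state, "prune_state"), t >= 0)
  if (!is_prune_step(t, scheds$w)) return(state)

  p_w <- sparsity_at(t, scheds$w)
  p_a <- sparsity_at(t, scheds$a)
  p_x <- sparsity_at(t, scheds$x)

  pw <- prune_weights(weights, state$m_w, p_w)
  state$m_w <- pw$m_w
  pa <- prune_edges(state$m_a, p_a)
  state$m_a <- pa$m_a
  px <- prune_features(state$m_x, p_x)
  state$m_x <- px$m_x
  state$p_w <- p_w; state$p_a <- p_a; state$p_x <- p_x

  rw <- regrow(state$m_w, grads$w, cfg, scores = abs(weights),
               new_value = 1, seed = derive_seed(seed, paste0("w", t)))
  state$m_w <- rw$mask
  ra <- regrow(state$m_a, grads$a, cfg,
               seed = derive_seed(seed, paste0("a", t)))
  state$m_a <- ra$mask
  rx <- regrow(state$m_x, grads$x, cfg,
               seed = derive_seed(seed, paste0("x", t)))
  state$m_x <- rx$mask
  attr(state, "weight_reset") <- rw$activated
  state
}

#' Sparsity report for a prune state
#'
#' @param state a `prune_state`.
#' @return Data frame with per-element candidate counts, retained counts and
#'   realized sparsities.
#' @export
prune_report <- function(state) {
  stopifnot(inherits(state, "prune_state"))
  data.frame(
    element = c("weights", "edges", "features"),
    candidates = c(length(state$m_w), length(state$m_a), length(state$m_x)),
    retained = c(sum(state$m_w != 0), sum(state$m_a != 0), sum(state$m_x != 0)),
    sparsity = c(state$p_w, state$p_a, state$p_x)
  )
}
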