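#' Parameters of the synthetic H&E-like tile generator
#'
#' The generator emulates the appearance drivers of stained lymph-node tissue
#' tiles: a pink multiscale stroma texture with scattered dark nuclei, zero or
#' more irregular metastatic blobs with darker and denser nuclear texture, a
#' per-tile global stain shift, and additive pixel noise. Masks are
#' pixel-exact unions of the blobs.
#'
#' @param size tile side length in pixels.
#' @param blob_count_range integer range of blob counts for positive tiles.
#' @param blob_area_fraction target total blob area as a fraction of the tile.
#' @param texture_scales grid spacings (pixels) of the multiscale value noise.
#' @param noise_sd standard deviation of the additive Gaussian pixel noise.
#' @param stain_brightness_sd sd of the per-tile multiplicative stain
#'   brightness factor (centered at 1).
#' @param stain_hue_sd sd of the per-tile additive per-channel stain shift.
#' @param nuclei_density background nuclei per pixel.
#' @param blob_nuclei_factor nuclei density multiplier inside blobs.
#' @param blob_contrast how much darker blob tissue is than stroma.
#' @param min_blob_radius smallest allowed mean blob radius (pixels).
#' @return A named list of class `tile_params`.
#' @export
tile_params <- function(size = 64L,
                        blob_count_range = c(1L, 3L),
                        blob_area_fraction = 0.2,
                        texture_scales = c(4, 8, 16),
                        noise_sd = 0.02,
                        stain_brightness_sd = 0.10,
                        stain_hue_sd = 0.04,
                        nuclei_density = 0.01,
                        blob_nuclei_factor = 3,
                        blob_contrast = 0.28,
                        min_blob_radius = 4) {
  if (blob_area_fraction >= 1) stop("blob area fraction must be < 1")
  stopifnot(size >= 16, blob_area_fraction >= 0)
  structure(as.list(environment()), class = "tile_params")
}

# Multiscale value noise in [0, 1]: random coarse grids bilinearly upsampled
# and summed with 1/scale amplitudes.
value_noise <- function(size, scales) {
  acc <- matrix(0, size, size)
  wsum <- 0
  for (s in scales) {
    g <- ceiling(size / s) + 1L
    coarse <- matrix(stats::runif(g * g), g, g)
    up <- scale_image(array(coarse, dim = c(g, g, 1L)),
                      s = size / g * 1.0001, interp = "bilinear")[, , 1L]
    up <- up[seq_len(min(nrow(up), size)), seq_len(min(ncol(up), size)), drop = FALSE]
    full <- matrix(0, size, size)
    full[seq_len(nrow(up)), seq_len(ncol(up))] <- up
    if (nrow(up) < size) full[(nrow(up) + 1):size, ] <- full[rep(nrow(up), size - nrow(up)), ]
    if (ncol(up) < size) full[, (ncol(up) + 1):size] <- full[, rep(ncol(up), size - ncol(up))]
    w <- 1 / s
    acc <- acc + w * full
    wsum <- wsum + w
  }
  acc <- acc / wsum
  rng <- range(acc)
  if (diff(rng) < 1e-12) return(acc * 0 + 0.5)
  (acc - rng[1L]) / diff(rng)
}

# Paint filled discs (nuclei) into an RGB array.
paint_discs <- function(img, centers, radius, color, strength = 0.85) {
  size <- dim(img)[1L]
  for (i in seq_len(nrow(centers))) {
    cy <- centers[i, 1L]; cx <- centers[i, 2L]; r <- radius[i]
    ys <- max(1L, floor(cy - r)):min(size, ceiling(cy + r))
    xs <- max(1L, floor(cx - r)):min(size, ceiling(cx + r))
    dy <- outer(ys - cy, rep(1, length(xs)))
    dx <- outer(rep(1, length(ys)), xs - cx)
    inside <- dy^2 + dx^2 <= r^2
    for (c in 1:3) {
      patch <- img[ys, xs, c]
      patch[inside] <- (1 - strength) * patch[inside] + strength * color[c]
      img[ys, xs, c] <- patch
    }
  }
  img
}

# One irregular blob mask: ellipse-like region whose radius is perturbed by a
# low-order radial Fourier series.
blob_mask <- function(size, center, r0, n_harmonics = 4L) {
  a <- stats::rnorm(n_harmonics, 0, 0.07)
  phi <- stats::runif(n_harmonics, 0, 2 * pi)
  rmax <- r0 * (1 + sum(abs(a))) + 1
  ys <- max(1L, floor(center[1L] - rmax)):min(size, ceiling(center[1L] + rmax))
  xs <- max(1L, floor(center[2L] - rmax)):min(size, ceiling(center[2L] + rmax))
  dy <- outer(ys - center[1L], rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - center[2L])
  theta <- atan2(dy, dx)
  rtheta <- r0 * (1 + Reduce(`+`, lapply(seq_len(n_harmonics), function(k) {
    a[k] * cos((k + 1) * theta + phi[k])
  })))
  inside <- sqrt(dy^2 + dx^2) <= rtheta
  mask <- matrix(FALSE, size, size)
  mask[ys, xs] <- inside
  mask
}

#' Generate one synthetic tile
#'
#' Deterministic in `(seed, params, label)`: the same inputs reproduce the
#' tile bit for bit.
#'
#' @param seed integer seed for this tile.
#' @param params a [tile_params()] record.
#' @param label 1 for a metastatic tile (1-3 blobs), 0 for a negative tile.
#' @return A list of class `synthetic_tile` with elements `image`
#'   (`size x size x 3` array in `[0, 1]`), `mask` (binary matrix), `label`,
#'   `seed`, and `params`.
#' @export
generate_tile <- function(seed, params = tile_params(), label = 1L) {
  stopifnot(inherits(params, "tile_params"), label %in% c(0L, 1L))
  with_seed(derive_seed(seed, "tile"), {
    size <- params$size
    stroma <- c(0.93, 0.74, 0.86)
    nucleus_col <- c(0.40, 0.20, 0.52)
    blob_col <- stroma - params$blob_contrast * c(0.9, 1.1, 0.6)

    tex <- value_noise(size, params$texture_scales)
    img <- array(0, dim = c(size, size, 3L))
    for (c in 1:3) img[, , c] <- stroma[c] * (0.82 + 0.30 * tex)

    mask <- matrix(0L, size, size)
    if (label == 1L) {
      nb <- sample(seq(params$blob_count_range[1L], params$blob_count_range[2L]), 1L)
      total_area <- params$blob_area_fraction * size^2
      shares <- stats::runif(nb, 0.7, 1.3)
      shares <- shares / sum(shares)
      for (b in seq_len(nb)) {
        r0 <- max(params$min_blob_radius, sqrt(shares[b] * total_area / pi))
        margin <- min(r0 * 1.45 + 1, size / 2 - 1)
        center <- stats::runif(2, margin + 1, size - margin)
        mask <- mask | blob_mask(size, center, r0)
      }
      mask <- matrix(as.integer(mask), size, size)
      # darker, denser metastatic tissue with its own finer texture
      tex2 <- value_noise(size, pmax(params$texture_scales / 2, 2))
      idx <- mask == 1L
      for (c in 1:3) {
        ch <- img[, , c]
        ch[idx] <- blob_col[c] * (0.80 + 0.35 * tex2[idx])
        img[, , c] <- ch
      }
    }

    # scattered nuclei: background density, boosted inside blobs
    n_bg <- stats::rpois(1L, params$nuclei_density * size^2)
    if (n_bg > 0) {
      centers <- cbind(stats::runif(n_bg, 2, size - 1), stats::runif(n_bg, 2, size - 1))
      img <- paint_discs(img, centers, stats::runif(n_bg, 1.0, 2.0), nucleus_col)
    }
    if (label == 1L && any(mask == 1L)) {
      pos <- which(mask == 1L, arr.ind = TRUE)
      n_in <- stats::rpois(1L, params$nuclei_density * params$blob_nuclei_factor * nrow(pos))
      if (n_in > 0) {
        pick <- pos[sample(nrow(pos), n_in, replace = TRUE), , drop = FALSE]
        img <- paint_discs(img, pick + matrix(stats::runif(2 * n_in, -0.5, 0.5), ncol = 2),
                           stats::runif(n_in, 0.8, 1.6), nucleus_col * 0.9)
      }
    }

    # per-tile stain variation: global brightness + per-channel shift
    bright <- stats::rnorm(1L, 1, params$stain_brightness_sd)
    shift <- stats::rnorm(3L, 0, params$stain_hue_sd)
    for (c in 1:3) img[, , c] <- img[, , c] * bright + shift[c]

    img <- img + array(stats::rnorm(length(img), 0, params$noise_sd), dim = dim(img))
    img <- pmin(pmax(img, 0), 1)

    label_out <- if (any(mask == 1L)) 1L else 0L
    structure(
      list(image = img, mask = mask, label = label_out, seed = seed, params = params),
      class = "synthetic_tile"
    )
  })
}

#' Generate a labeled dataset of synthetic tiles
#'
#' Produces `n` tiles with exactly `round(n * pos_fraction)` positives. The
#' default positive fraction 0.315 mirrors a typical metastatic/normal
#' training ratio of roughly 126:274. One master seed spawns an independent
#' per-tile stream, so tiles are reproducible individually and in parallel.
#'
#' @param n number of tiles.
#' @param pos_fraction fraction of metastatic tiles.
#' @param seed master seed.
#' @param params a [tile_params()] record.
#' @param dir optional output directory; when given, writes `tile_###.png`,
#'   `mask_###.png`, a `manifest.csv` (tile_id, label, seed) and a
#'   `params.json` sidecar.
#' @return List with `tiles` (list of [generate_tile()] outputs) and
#'   `manifest` (data frame).
#' @export
generate_dataset <- function(n, pos_fraction = 0.315, seed = 1L,
                             params = tile_params(), dir = NULL) {
  stopifnot(n >= 1, pos_fraction >= 0, pos_fraction <= 1)
  n_pos <- round(n * pos_fraction)
  labels <- integer(n)
  pos_idx <- with_seed(derive_seed(seed, "labels"), sample(n, n_pos))
  labels[pos_idx] <- 1L
  seeds <- vapply(seq_len(n), function(i) derive_seed(seed, paste0("tile-", i)), 1L)
  tiles <- lapply(seq_len(n), function(i) generate_tile(seeds[i], params, labels[i]))
  manifest <- data.frame(
    tile_id = sprintf("tile_%04d", seq_len(n)),
    label = vapply(tiles, function(t) t$label, 1L),
    seed = seeds
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      write_tile(tiles[[i]]$image, file.path(dir, paste0(manifest$tile_id[i], ".png")))
      write_tile(array(tiles[[i]]$mask, dim = c(dim(tiles[[i]]$mask), 1L)),
                 file.path(dir, paste0("mask_", sprintf("%04d", i), ".png")))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    jsonlite::write_json(params[names(params) != "class"],
                         file.path(dir, "params.json"), auto_unbox = TRUE)
  }
  list(tiles = tiles, manifest = manifest)
}
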