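#' Image containers
#'
#' Images are plain numeric arrays: either an `H x W` matrix (grayscale) or an
#' `H x W x C` array. 8-bit integer input is rescaled to `[0, 1]` on read;
#' after [normalize_image()] values are unconstrained z-scores.
#'
#' @param x numeric matrix or 3-d array of pixel intensities.
#' @return A validated image array (invisibly the same object).
#' @export
as_image <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(is.array(x), length(dim(x)) == 3L, all(dim(x) >= 1L), is.numeric(x))
  x
}

n_channels <- function(img) dim(as_image(img))[3L]

#' Z-score normalization of a tile
#'
#' Standardizes each channel to zero mean and unit standard deviation using
#' the population statistics of the whole channel. Constant channels (sigma
#' below `1e-8`) map to all zeros instead of dividing by zero.
#'
#' @param img an image array (see [as_image()]).
#' @return Image of the same shape with per-channel mean 0 and sd 1 (where the
#'   input had non-degenerate spread).
#' @export
normalize_image <- function(img) {
  img <- as_image(img)
  for (c in seq_len(dim(img)[3L])) {
    ch <- img[, , c]
    mu <- mean(ch)
    sd_pop <- sqrt(mean((ch - mu)^2))
    img[, , c] <- (ch - mu) / max(sd_pop, 1e-8)
    if (sd_pop <= 1e-8) img[, , c] <- 0
  }
  img
}

#' Averaging / Gaussian filter kernels
#'
#' @param k odd kernel size.
#' @param method `"gaussian"` or `"average"`.
#' @param sigma Gaussian bandwidth in pixels; default `k / 4`.
#' @return `k x k` matrix of nonnegative weights summing to 1.
#' @export
filter_kernel <- function(k, method = c("gaussian", "average"), sigma = k / 4) {
  method <- match.arg(method)
  stopifnot(k >= 1, k %% 2 == 1)
  if (method == "average") {
    w <- matrix(1, k, k)
  } else {
    r <- seq_len(k) - (k + 1) / 2
    g <- exp(-r^2 / (2 * sigma^2))
    w <- outer(g, g)
  }
  w / sum(w)
}

# Reflection (symmetric) padding indices for length n, pad p.
reflect_idx <- function(n, p) {
  stopifnot(p < n || p == 0)
  c(rev(seq_len(p)), seq_len(n), n - seq_len(p) + 1L)
}

# Stack the k^2 shifted copies of a reflected-padded matrix as columns of an
# (H*W) x k^2 matrix; shared workhorse of the linear and median filters.
neighborhood_matrix <- function(ch, k) {
  h <- nrow(ch); w <- ncol(ch); p <- (k - 1L) %/% 2L
  pad <- ch[reflect_idx(h, p), reflect_idx(w, p), drop = FALSE]
  out <- matrix(0, h * w, k * k)
  col <- 1L
  for (dj in seq_len(k)) {
    for (di in seq_len(k)) {
      out[, col] <- as.vector(pad[di:(di + h - 1L), dj:(dj + w - 1L)])
      col <- col + 1L
    }
  }
  out
}

#' Noise reduction by Gaussian or median filtering
#'
#' Applies a weighted neighborhood sum (Gaussian/averaging kernel) or the
#' neighborhood median over a `k x k` window. Borders are handled by
#' reflection so constant images are exactly preserved.
#'
#' @param img image array.
#' @param k odd window size, `k <= min(height, width)`.
#' @param method `"gaussian"` or `"median"`.
#' @param kernel optional explicit kernel matrix (overrides `k` for the
#'   Gaussian path); must be square, odd-sized, nonnegative.
#' @return Filtered image of the same shape.
#' @export
denoise <- function(img, k = 3, method = c("gaussian", "median"), kernel = NULL) {
  method <- match.arg(method)
  img <- as_image(img)
  if (!is.null(kernel)) {
    stopifnot(is.matrix(kernel), nrow(kernel) == ncol(kernel))
    k <- nrow(kernel)
  }
  if (k %% 2 == 0) stop("kernel size k must be odd")
  if (k > min(dim(img)[1:2])) stop("kernel size exceeds image size")
  if (k == 1L) return(img)
  if (method == "gaussian" && is.null(kernel)) kernel <- filter_kernel(k, "gaussian")
  h <- dim(img)[1L]; w <- dim(img)[2L]
  for (c in seq_len(dim(img)[3L])) {
    nb <- neighborhood_matrix(img[, , c], k)
    img[, , c] <- if (method == "median") {
      matrix(apply(nb, 1L, stats::median), h, w)
    } else {
      matrix(nb %*% as.vector(kernel), h, w)
    }
  }
  img
}

#' Augmentation configuration
#'
#' The default realizes five variants per tile: one 90-degree rotation, a
#' horizontal and a vertical flip, and scalings by 0.9 and 1.1.
#'
#' @param rotation_angles rotation angles in degrees (counterclockwise).
#' @param scale_factors positive rescaling factors.
#' @param flip_horizontal,flip_vertical include the mirrored variants.
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(rotation_angles = 90,
                           scale_factors = c(0.9, 1.1),
                           flip_horizontal = TRUE,
                           flip_vertical = TRUE) {
  if (any(scale_factors <= 0)) stop("scale factors must be positive")
  structure(
    list(
      rotation_angles = rotation_angles, scale_factors = scale_factors,
      flip_horizontal = isTRUE(flip_horizontal),
      flip_vertical = isTRUE(flip_vertical)
    ),
    class = "augment_config"
  )
}

rot90_ccw <- function(m) {
  t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
}

#' Rotate an image about its center
#'
#' Multiples of 90 degrees are exact pixel permutations; other angles use the
#' inverse coordinate map with bilinear (images) or nearest-neighbor (masks)
#' resampling, padding with the image mean outside the support.
#'
#' @param img image array.
#' @param theta angle in degrees, counterclockwise.
#' @param interp `"bilinear"` or `"nearest"`.
#' @return Rotated image (same size except for the 90/270 transpose of
#'   non-square inputs).
#' @export
rotate_image <- function(img, theta, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  img <- as_image(img)
  a <- ((theta %% 360) + 360) %% 360
  if (a %in% c(0, 90, 180, 270)) {
    out <- img
    for (r in seq_len(a / 90)) {
      nc <- dim(out)[3L]
      rot <- lapply(seq_len(nc), function(c) rot90_ccw(out[, , c]))
      out <- array(unlist(rot), dim = c(dim(rot[[1L]]), nc))
    }
    return(out)
  }
  h <- dim(img)[1L]; w <- dim(img)[2L]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- theta * pi / 180
  # inverse map: rotate output coordinates by -theta around the center
  gy <- rep(seq_len(h), times = w) - cy
  gx <- rep(seq_len(w), each = h) - cx
  sx <- cos(th) * gx + sin(th) * gy + cx
  sy <- -sin(th) * gx + cos(th) * gy + cy
  sample_grid(img, sy, sx, interp)
}

# Sample image at fractional (row, col) positions; constant fill outside.
sample_grid <- function(img, sy, sx, interp) {
  h <- dim(img)[1L]; w <- dim(img)[2L]; nc <- dim(img)[3L]
  out <- array(0, dim = c(h, w, nc))
  for (c in seq_len(nc)) {
    ch <- img[, , c]
    fill <- mean(ch)
    if (interp == "nearest") {
      ri <- round(sy); ci <- round(sx)
      ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
      v <- rep(fill, length(sy))
      v[ok] <- ch[cbind(ri[ok], ci[ok])]
    } else {
      r0 <- floor(sy); c0 <- floor(sx)
      fr <- sy - r0; fc <- sx - c0
      v <- rep(fill, length(sy))
      ok <- r0 >= 1 & r0 + 1 <= h & c0 >= 1 & c0 + 1 <= w
      if (any(ok)) {
        r0k <- r0[ok]; c0k <- c0[ok]; frk <- fr[ok]; fck <- fc[ok]
        v[ok] <- ch[cbind(r0k, c0k)] * (1 - frk) * (1 - fck) +
          ch[cbind(r0k + 1, c0k)] * frk * (1 - fck) +
          ch[cbind(r0k, c0k + 1)] * (1 - frk) * fck +
          ch[cbind(r0k + 1, c0k + 1)] * frk * fck
      }
      # clamp samples that fall on the last row/col line
      edge <- !ok & sy >= 1 & sy <= h & sx >= 1 & sx <= w
      if (any(edge)) {
        v[edge] <- ch[cbind(pmin(pmax(round(sy[edge]), 1), h),
                            pmin(pmax(round(sx[edge]), 1), w))]
      }
    }
    out[, , c] <- matrix(v, h, w)
  }
  out
}

#' Rescale an image by a positive factor
#'
#' @param img image array.
#' @param s positive scale factor; output size is `round(dim * s)`.
#' @param interp resampling scheme.
#' @return Resized image.
#' @export
scale_image <- function(img, s, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  if (s <= 0) stop("scale factor must be positive")
  img <- as_image(img)
  h <- dim(img)[1L]; w <- dim(img)[2L]; nc <- dim(img)[3L]
  nh <- max(1L, round(h * s)); nw <- max(1L, round(w * s))
  if (nh == h && nw == w && abs(s - 1) < 1e-12) return(img)
  sy <- ((seq_len(nh) - 0.5) * h / nh) + 0.5 - 0.5
  sx <- ((seq_len(nw) - 0.5) * w / nw) + 0.5 - 0.5
  sy <- pmin(pmax(sy, 1), h); sx <- pmin(pmax(sx, 1), w)
  gy <- rep(sy, times = nw); gx <- rep(sx, each = nh)
  sample_grid_resize(img, gy, gx, nh, nw, interp)
}

sample_grid_resize <- function(img, sy, sx, nh, nw, interp) {
  h <- dim(img)[1L]; w <- dim(img)[2L]; nc <- dim(img)[3L]
  out <- array(0, dim = c(nh, nw, nc))
  for (c in seq_len(nc)) {
    ch <- img[, , c]
    if (interp == "nearest") {
      v <- ch[cbind(pmin(pmax(round(sy), 1), h), pmin(pmax(round(sx), 1), w))]
    } else {
      r0 <- pmin(pmax(floor(sy), 1), h - 1L); c0 <- pmin(pmax(floor(sx), 1), w - 1L)
      if (h == 1L) r0 <- rep(1L, length(sy))
      if (w == 1L) c0 <- rep(1L, length(sx))
      fr <- pmin(pmax(sy - r0, 0), 1); fc <- pmin(pmax(sx - c0, 0), 1)
      r1 <- pmin(r0 + 1L, h); c1 <- pmin(c0 + 1L, w)
      v <- ch[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
        ch[cbind(r1, c0)] * fr * (1 - fc) +
        ch[cbind(r0, c1)] * (1 - fr) * fc +
        ch[cbind(r1, c1)] * fr * fc
    }
    out[, , c] <- matrix(v, nh, nw)
  }
  out
}

flip_image <- function(img, horizontal = TRUE) {
  img <- as_image(img)
  if (horizontal) img[, rev(seq_len(dim(img)[2L])), , drop = FALSE]
  else img[rev(seq_len(dim(img)[1L])), , , drop = FALSE]
}

#' Augment a tile into additional variants
#'
#' Produces one variant per enabled transform (the original is not included).
#' The default configuration yields exactly five variants.
#'
#' @param img image array.
#' @param cfg an [augment_config()].
#' @param interp resampling for rotations/scalings (`"nearest"` for masks).
#' @return List of image arrays, named by transform.
#' @export
augment <- function(img, cfg = augment_config(), interp = "bilinear") {
  stopifnot(inherits(cfg, "augment_config"))
  img <- as_image(img)
  out <- list()
  for (a in cfg$rotation_angles) {
    out[[paste0("rot", a)]] <- rotate_image(img, a, interp)
  }
  if (cfg$flip_horizontal) out[["fliph"]] <- flip_image(img, TRUE)
  if (cfg$flip_vertical) out[["flipv"]] <- flip_image(img, FALSE)
  for (s in cfg$scale_factors) {
    out[[paste0("scale", s)]] <- scale_image(img, s, interp)
  }
  out
}

#' Read / write tiles
#'
#' PNG via the `png` package (values in `[0, 1]`); TIFF via `tiff` when
#' installed.
#'
#' @param path file path ending in `.png` or `.tif(f)`.
#' @return `read_tile` returns an image array.
#' @export
read_tile <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("tiff package not installed")
    x <- tiff::readTIFF(path)
  } else {
    x <- png::readPNG(path)
  }
  as_image(x)
}

#' @rdname read_tile
#' @param img image array with values in `[0, 1]` (clamped on write).
#' @export
write_tile <- function(img, path) {
  img <- as_image(img)
  img <- pmin(pmax(img, 0), 1)
  if (dim(img)[3L] == 1L) img <- img[, , 1L]
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("tiff package not installed")
    tiff::writeTIFF(img, path)
  } else {
    png::writePNG(img, path)
  }
  invisible(path)
}
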