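#' @keywords internal
"_PACKAGE"

# Numerically stable row-wise softmax.
softmax_rows <- function(u) {
  m <- apply(u, 1L, max)
  e <- exp(u - m)
  e / rowSums(e)
}

leaky_relu <- function(x, slope = 0.01) {
  ifelse(x >= 0, x, slope * x)
}

leaky_relu_grad <- function(x, slope = 0.01) {
  ifelse(x >= 0, 1, slope)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Derive a 32-bit sub-seed from a master seed and a stream label, so that
# independent stages (tiles, weight init, batching) get decoupled streams.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  key <- paste0(stream, ":", format(seed, scientific = FALSE))
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(max(h, 1))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
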