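# Internal tensor helpers.  Activation volumes are numeric arrays with dim
# (H, W, C) for a single feature map or (H, W, C, N) for a batch.

as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("expected an H x W x C feature map or an H x W x C x N batch")
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

unbatch_like <- function(y, x_was_3d) {
  if (x_was_3d) {
    d <- dim(y)
    dim(y) <- d[1:3]
  }
  y
}

# broadcast a per-channel vector over an (H, W, C, N) array
bcast_channel <- function(v, d) {
  array(rep(rep(v, each = d[1] * d[2]), times = d[4]), dim = d)
}

relu6_bwd <- function(z, dy) dy * (z > 0 & z < 6)

# Batch normalization over (H, W, N) per channel; biased variance, eps fixed.
bn_eps <- 1e-5

# normalized binomial blur kernel used by MaxBlurPool
blur_kernel <- function(size = 3L) {
  stopifnot(size >= 2)
  v <- choose(size - 1, 0:(size - 1))
  k <- outer(v, v)
  k <- k / sum(k)
  dim(k) <- c(size, size)
  k
}

# spatial softmax over the H x W positions of each (group, sample) slice
spatial_softmax <- function(z) {
  d <- dim(z)  # (H, W, G, N)
  zm <- matrix(z, d[1] * d[2], d[3] * d[4])
  zm <- exp(sweep(zm, 2, apply(zm, 2, max), "-"))
  zm <- sweep(zm, 2, colSums(zm), "/")
  array(zm, dim = d)
}

spatial_softmax_bwd <- function(m, dm) {
  d <- dim(m)
  mm <- matrix(m, d[1] * d[2], d[3] * d[4])
  dmm <- matrix(dm, d[1] * d[2], d[3] * d[4])
  dz <- mm * sweep(dmm, 2, colSums(dmm * mm), "-")
  array(dz, dim = d)
}

# run code with a private RNG stream, leaving the caller's stream untouched
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
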