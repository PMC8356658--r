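# Sub-feature space attention module (SFSAM).
#
# The C input channels are split into g contiguous groups.  Each group is
# summarized by per-position channel max and channel mean, the two-channel
# descriptor passes through a k x k convolution (one filter bank per group),
# and the result is gated -- by default with a softmax over all H x W
# positions, so every group's attention map is a spatial probability
# distribution.  The map re-weights its group residually:
# F_hat = (M (x) F) (+) F.

#' Attention module configuration
#'
#' @param groups Number of mutually exclusive channel groups `g`.
#' @param kernel Spatial size of the attention convolution (odd).
#' @param per_group_filters If `TRUE` (default) each group learns its own
#'   `kernel x kernel x 2` filter and bias; if `FALSE` one filter bank is
#'   shared across groups.
#' @param gate Gating nonlinearity: `"softmax"` (default) normalizes each
#'   group's map over all spatial positions so it sums to one; `"sigmoid"`
#'   gates each position independently into (0, 1).
#' @return An object of class `attention_config`.
#' @export
attention_config <- function(groups = 4L, kernel = 7L,
                             per_group_filters = TRUE,
                             gate = c("softmax", "sigmoid")) {
  gate <- match.arg(gate)
  groups <- as.integer(groups)
  kernel <- as.integer(kernel)
  if (groups < 1) stop("attention_config: groups must be >= 1")
  if (kernel %% 2L == 0L) stop("attention_config: kernel must be odd")
  structure(list(groups = groups, kernel = kernel,
                 per_group_filters = per_group_filters, gate = gate),
            class = "attention_config")
}

#' Split a feature map into contiguous channel groups
#'
#' @param f An `H x W x C` feature map (or `H x W x C x N` batch).
#' @param g Number of groups; `C` must be divisible by `g`.
#' @param site Optional site label used in the error message when the
#'   channel count is not divisible by `g`.
#' @return A list of `g` sub-feature maps in channel order; concatenating
#'   them along the channel axis recovers `f` exactly.
#' @export
split_groups <- function(f, g, site = "feature map") {
  d <- dim(f)
  if (is.null(d) || length(d) < 3) stop("split_groups: need an H x W x C array")
  C <- d[3]
  if (C %% g != 0)
    stop(sprintf("split_groups: %s has %d channels, not divisible by g = %d",
                 site, C, g))
  n <- C %/% g
  was3 <- length(d) == 3L
  fb <- as_batch(f)
  lapply(seq_len(g), function(i) {
    unbatch_like(slice_channels(fb, (i - 1L) * n + 1L, n), was3)
  })
}

#' Channel-axis pooling descriptor
#'
#' Computes the per-position maximum and mean over channels, the two-channel
#' descriptor that drives each group's attention map.
#'
#' @param f_i A sub-feature map `H x W x n` (or batched).
#' @return An `H x W x 2` array (or batched): channel 1 is the channel-wise
#'   maximum, channel 2 the channel-wise mean.
#' @export
channel_pool <- function(f_i) {
  d <- dim(f_i)
  was3 <- length(d) == 3L
  x <- as_batch(f_i)
  d <- dim(x)
  pooled <- channel_pool_batch(x)
  unbatch_like(pooled$desc, was3)
}

# internal: returns descriptor plus channel argmax (for backprop)
channel_pool_batch <- function(x) .group_channel_pool(x, 1L)

#' Compute one group's spatial attention map
#'
#' Applies a `k x k` convolution (2 input channels, 1 output channel, with
#' bias) to a channel-pooling descriptor and gates the result.  Under the
#' default softmax gate the returned map is non-negative and sums to one
#' over all spatial positions.
#'
#' @param descriptor An `H x W x 2` descriptor from [channel_pool()].
#' @param config An [attention_config()].
#' @param weights Optional list with elements `W` (`k x k x 2 x 1`) and `b`
#'   (length 1); freshly initialized when omitted.
#' @return An `H x W` attention map.
#' @export
attention_map <- function(descriptor, config = attention_config(),
                          weights = NULL) {
  k <- config$kernel
  if (is.null(weights))
    weights <- list(W = array(stats::rnorm(k * k * 2, sd = 0.01),
                              dim = c(k, k, 2L, 1L)),
                    b = 0)
  was3 <- length(dim(descriptor)) == 3L
  x <- as_batch(descriptor)
  if (dim(x)[3] != 2L) stop("attention_map: descriptor must have 2 channels")
  z <- .conv2d_fwd(x, weights$W, as.numeric(weights$b), 1L)
  m <- if (config$gate == "softmax") spatial_softmax(z) else 1 / (1 + exp(-z))
  d <- dim(m)
  if (was3) array(m, dim = d[1:2]) else m
}

#' Residual attention re-weighting
#'
#' The refinement step `F_hat = (M (x) F) (+) F`: each group's single-channel
#' map is broadcast across the group's channels, multiplied element-wise with
#' the group and added back to it.  With all-zero maps this is exactly the
#' identity.
#'
#' @param f An `H x W x C` feature map (or batch).
#' @param maps An `H x W x g` array of group attention maps (or batch).
#' @return The refined feature map, same shape as `f`.
#' @export
apply_attention <- function(f, maps) {
  was3 <- length(dim(f)) == 3L
  x <- as_batch(f)
  m <- as_batch(maps)
  d <- dim(x)
  g <- dim(m)[3]
  if (d[3] %% g != 0) stop("apply_attention: channels not divisible by groups")
  n <- d[3] %/% g
  mfull <- array(0, dim = d)
  for (c in seq_len(d[3])) {
    i <- (c - 1L) %/% n + 1L
    mfull[, , c, ] <- m[, , i, ]
  }
  unbatch_like(x * (1 + mfull), was3)
}

#' Forward pass of the sub-feature space attention module
#'
#' @param f An `H x W x C` feature map (or `H x W x C x N` batch).
#' @param config An [attention_config()]; `C` must be divisible by
#'   `config$groups`.
#' @param weights Optional list with `W` (`k x k x 2 x g`) and `b`
#'   (length `g`); freshly initialized when omitted.
#' @return The refined feature map, same `H`, `W`, `C` as the input.  The
#'   attention layer used is attached as attribute `"layer"`.
#' @export
sfsam_forward <- function(f, config = attention_config(), weights = NULL) {
  was3 <- length(dim(f)) == 3L
  x <- as_batch(f)
  C <- dim(x)[3]
  ly <- new_sfsam(C, config)
  if (!is.null(weights)) {
    ly$params$W <- weights$W
    ly$params$b <- as.numeric(weights$b)
  }
  y <- sfsam_layer_forward(ly, x, training = FALSE)
  y <- unbatch_like(y, was3)
  attr(y, "layer") <- ly
  y
}

# ---------------------------------------------------------------- the layer

new_sfsam <- function(C, config, name = "sfsam") {
  g <- config$groups
  if (C %% g != 0)
    stop(sprintf("SFSAM site '%s': %d channels not divisible by g = %d",
                 name, C, g))
  ly <- new_layer("sfsam", name)
  ly$C <- as.integer(C)
  ly$config <- config
  k <- config$kernel
  nf <- if (config$per_group_filters) g else 1L
  ly$params$W <- array(stats::rnorm(k * k * 2 * nf, sd = 0.01),
                       dim = c(k, k, 2L, nf))
  ly$params$b <- numeric(nf)
  ly
}

sfsam_group_weights <- function(ly, i) {
  if (ly$config$per_group_filters) i else 1L
}

sfsam_layer_forward <- function(ly, x, training) {
  d <- dim(x)
  g <- ly$config$groups
  k <- ly$config$kernel
  pool <- .group_channel_pool(x, g)
  z <- array(0, dim = c(d[1], d[2], g, d[4]))
  for (i in seq_len(g)) {
    desc_i <- .channel_slice(pool$desc, 2L * i - 1L, 2L)
    wi <- sfsam_group_weights(ly, i)
    Wg <- array(ly$params$W[, , , wi], dim = c(k, k, 2L, 1L))
    z[, , i, ] <- .conv2d_fwd(desc_i, Wg, ly$params$b[wi], 1L)
  }
  m <- if (ly$config$gate == "softmax") spatial_softmax(z)
       else 1 / (1 + exp(-z))
  if (training)
    ly$cache <- list(x = x, m = m, desc = pool$desc, amax = pool$amax)
  .group_gate_fwd(x, m, g)
}

sfsam_layer_backward <- function(ly, dy) {
  cc <- ly$cache
  d <- dim(dy)
  g <- ly$config$groups
  k <- ly$config$kernel
  gb <- .group_gate_bwd(cc$x, cc$m, dy, g)
  dz <- if (ly$config$gate == "softmax") spatial_softmax_bwd(cc$m, gb$dm)
        else gb$dm * cc$m * (1 - cc$m)
  nf <- dim(ly$params$W)[4]
  dW <- array(0, dim = dim(ly$params$W))
  db <- numeric(nf)
  ddesc <- array(0, dim = c(d[1], d[2], 2L * g, d[4]))
  for (i in seq_len(g)) {
    wi <- sfsam_group_weights(ly, i)
    Wg <- array(ly$params$W[, , , wi], dim = c(k, k, 2L, 1L))
    dzi <- array(dz[, , i, ], dim = c(d[1], d[2], 1L, d[4]))
    desc_i <- .channel_slice(cc$desc, 2L * i - 1L, 2L)
    cv <- .conv2d_bwd(desc_i, Wg, dzi, 1L, TRUE)
    dW[, , , wi] <- dW[, , , wi] + array(cv$dw, dim = c(k, k, 2L))
    db[wi] <- db[wi] + cv$db
    ddesc[, , (2L * i - 1L):(2L * i), ] <- cv$dx
  }
  dx <- .group_pool_bwd(gb$dx, ddesc, cc$amax, g)
  ly$grads$W <- dW
  ly$grads$b <- db
  ly$cache <- NULL
  dx
}
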