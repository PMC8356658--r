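# Core building blocks: the conv/BN/activation primitive, the dual-branch
# Root-module stem, the Shield-block, and anti-aliased MaxBlurPool
# downsampling.
#
# Channel bookkeeping of the Shield-block (width C_out, reduction rate t,
# split ratio r = 6):
#   hidden = round(C_out / t)                 bottleneck of the main branch
#   sub    = floor(C_out / r)                 sub-branch output channels
#   main   = C_out - sub                      main-branch output channels
# so the two branches concatenate back to exactly C_out.  The identity
# shortcut is only legal when in_channels == out_channels.

#' Convolution + batch normalization + activation
#'
#' The shared primitive of all blocks: a "same"-padded convolution
#' (optionally depthwise), batch normalization between convolution and
#' activation, and a ReLU6 (`min(max(x, 0), 6)`) or linear activation.
#'
#' When called without `weights` a freshly-initialized layer is created
#' (seed the RNG for reproducibility) and applied in inference mode, where
#' batch normalization uses its running statistics (identity at
#' initialization).  The layer object is attached as attribute `"layer"`.
#'
#' @param x An `H x W x C` feature map or `H x W x C x N` batch.
#' @param filters Number of output channels (must equal `C` when
#'   `depthwise = TRUE`).
#' @param kernel Kernel size, one of 1, 3, 7.
#' @param stride Stride, 1 or 2 ("same" padding: output is `ceil(H/stride)`).
#' @param depthwise Use a per-channel spatial convolution.
#' @param activation `"relu6"` or `"linear"`.
#' @param use_bias Include a convolution bias (default `TRUE`).
#' @param use_bn Apply batch normalization (default `TRUE`).
#' @param layer Optional pre-built layer to apply (overrides all other
#'   hyperparameters).
#' @return The output feature map, same rank as `x`.
#' @export
conv_bn_act <- function(x, filters, kernel = 3L, stride = 1L,
                        depthwise = FALSE,
                        activation = c("relu6", "linear"),
                        use_bias = TRUE, use_bn = TRUE, layer = NULL) {
  activation <- match.arg(activation)
  was3 <- length(dim(x)) == 3L
  xb <- as_batch(x)
  if (is.null(layer))
    layer <- new_cba(dim(xb)[3], filters, as.integer(kernel),
                     as.integer(stride), depthwise, activation,
                     use_bias, use_bn)
  y <- cba_forward(layer, xb, training = FALSE)
  y <- unbatch_like(y, was3)
  attr(y, "layer") <- layer
  y
}

#' Shield-block channel bookkeeping
#'
#' @param in_channels,out_channels Block input/output channel counts.
#' @param reduction_t Channel reduction rate `t` of the main-branch
#'   bottleneck (`hidden = round(out_channels / t)`); 2 for the
#'   channel-expanding first block of a stage, 6 otherwise.
#' @param split_r Split ratio `r`: the sub-branch carries
#'   `floor(out_channels / r)` of the output channels (default 6).
#' @param use_shortcut Add the identity shortcut (requires
#'   `in_channels == out_channels`).
#' @return An object of class `shield_block_spec` with derived fields
#'   `hidden`, `main`, `sub`.
#' @export
shield_block_spec <- function(in_channels, out_channels, reduction_t,
                              split_r = 6L, use_shortcut = FALSE) {
  in_channels <- as.integer(in_channels)
  out_channels <- as.integer(out_channels)
  if (use_shortcut && in_channels != out_channels)
    stop("shield_block_spec: shortcut requires in_channels == out_channels")
  hidden <- as.integer(round(out_channels / reduction_t))
  sub <- out_channels %/% as.integer(split_r)
  main <- out_channels - sub
  if (hidden < 1) stop("shield_block_spec: bottleneck width collapsed to 0")
  if (sub < 1) stop("shield_block_spec: sub-branch width collapsed to 0")
  structure(list(in_channels = in_channels, out_channels = out_channels,
                 reduction_t = as.integer(reduction_t),
                 split_r = as.integer(split_r),
                 use_shortcut = use_shortcut,
                 hidden = hidden, main = main, sub = sub),
            class = "shield_block_spec")
}

#' Apply a Shield-block
#'
#' Dual-branch inverted-residual-style block.  Main branch:
#' depthwise 3x3 (ReLU6) -> pointwise reduce to `hidden` (linear) ->
#' pointwise expand to `main` (ReLU6) -> depthwise 3x3 (linear).  Sub
#' branch: depthwise 3x3 (ReLU6) -> pointwise to `sub` (ReLU6).  The two
#' branches are concatenated; with `use_shortcut` the input is added
#' element-wise.
#'
#' @param x Feature map with `spec$in_channels` channels.
#' @param spec A [shield_block_spec()].
#' @param layer Optional pre-built layer to apply.
#' @return Feature map with `spec$out_channels` channels, spatial size
#'   unchanged; layer attached as attribute `"layer"`.
#' @export
shield_block <- function(x, spec, layer = NULL) {
  was3 <- length(dim(x)) == 3L
  xb <- as_batch(x)
  if (dim(xb)[3] != spec$in_channels)
    stop("shield_block: input has ", dim(xb)[3], " channels, spec expects ",
         spec$in_channels)
  if (is.null(layer)) layer <- new_shield(spec)
  y <- shield_forward(layer, xb, training = FALSE)
  y <- unbatch_like(y, was3)
  attr(y, "layer") <- layer
  y
}

#' Anti-aliased max pooling (MaxBlurPool)
#'
#' Dense (stride-1) 2x2 max pooling with edge replication, a fixed
#' normalized binomial blur kernel (reflect padding, no learnable
#' parameters), then stride-2 subsampling.  Output spatial size is
#' `ceil(H/2) x ceil(W/2)`; channels are unchanged.  Constant inputs are
#' mapped to the same constant.
#'
#' @param x Feature map with `H, W >= 2`.
#' @param blur_size Size of the binomial blur kernel (default 3, i.e.
#'   `[1,2,1]' [1,2,1] / 16`).
#' @return The downsampled feature map.
#' @export
max_blur_pool <- function(x, blur_size = 3L) {
  was3 <- length(dim(x)) == 3L
  xb <- as_batch(x)
  ly <- new_mbp(as.integer(blur_size))
  unbatch_like(mbp_forward(ly, xb, training = FALSE), was3)
}

#' Plain max pooling (reference operator)
#'
#' Non-overlapping 2x2/stride-2 max pooling, the conventional downsampler
#' that MaxBlurPool replaces; exposed so the two operators' shift
#' consistency can be compared.
#'
#' @param x Feature map with `H, W >= 2`.
#' @return The downsampled feature map (`ceil(H/2) x ceil(W/2)`).
#' @export
max_pool2 <- function(x) {
  was3 <- length(dim(x)) == 3L
  xb <- as_batch(x)
  mp <- .maxpool2_s1_fwd(xb)$y
  d <- dim(mp)
  ho <- seq(1L, d[1], by = 2L)
  wo <- seq(1L, d[2], by = 2L)
  unbatch_like(mp[ho, wo, , , drop = FALSE], was3)
}

#' Apply the Root-module stem
#'
#' First stage of the network: a 3x3 convolution with `stem_filters`
#' filters extracts shallow features; branch 1 downsamples them with
#' MaxBlurPool, branch 2 applies a 3x3/stride-2 convolution with
#' `branch_filters` filters followed by a 1x1 convolution reducing back to
#' `stem_filters`; the branches are concatenated to `2 * stem_filters`
#' channels at half resolution.
#'
#' @param x An `H x W x 3` image (or batch); `H`, `W` even.
#' @param stem_filters Width of the stem convolution (default 16).
#' @param branch_filters Width of the branch-2 3x3/stride-2 convolution
#'   before its 1x1 reduction (default 56).
#' @param in_channels Expected input channel count (default 3, RGB).
#' @param layer Optional pre-built layer to apply.
#' @return An `(H/2) x (W/2) x (2 * stem_filters)` feature map; layer
#'   attached as attribute `"layer"`.
#' @export
root_module <- function(x, stem_filters = 16L, branch_filters = 56L,
                        in_channels = 3L, layer = NULL) {
  was3 <- length(dim(x)) == 3L
  xb <- as_batch(x)
  d <- dim(xb)
  if (d[3] != in_channels)
    stop("root_module: expected ", in_channels, "-channel input, got ", d[3])
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L)
    stop("root_module: input spatial dims must be even")
  if (is.null(layer))
    layer <- new_root(in_channels, as.integer(stem_filters),
                      as.integer(branch_filters))
  y <- root_forward(layer, xb, training = FALSE)
  y <- unbatch_like(y, was3)
  attr(y, "layer") <- layer
  y
}
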