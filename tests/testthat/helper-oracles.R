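# Independent reference implementations used as oracles.  These are written
# as straight-line R translations of the definitions and are deliberately
# kept separate from the package's compute path.

rand_feature <- function(h, w, c, n = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n)) array(stats::rnorm(h * w * c), dim = c(h, w, c))
  else array(stats::rnorm(h * w * c * n), dim = c(h, w, c, n))
}

# "same"-padded convolution by direct summation (output ceil(H/stride),
# asymmetric padding with the extra row/column at the bottom/right)
naive_conv2d <- function(x, w, stride = 1, bias = NULL) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Cout <- dim(w)[4]
  Ho <- ceiling(H / stride); Wo <- ceiling(W / stride)
  ph <- max((Ho - 1) * stride + kh - H, 0) %/% 2
  pw <- max((Wo - 1) * stride + kw - W, 0) %/% 2
  y <- array(0, c(Ho, Wo, Cout))
  for (o in 1:Cout) for (ho in 1:Ho) for (wo in 1:Wo) {
    acc <- if (is.null(bias)) 0 else bias[o]
    for (i in 1:kh) for (j in 1:kw) {
      hi <- (ho - 1) * stride + i - ph
      wi <- (wo - 1) * stride + j - pw
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
        acc <- acc + sum(w[i, j, , o] * x[hi, wi, ])
    }
    y[ho, wo, o] <- acc
  }
  y
}

naive_dwconv2d <- function(x, w, stride = 1, bias = NULL) {
  C <- dim(x)[3]
  out <- NULL
  for (c in 1:C) {
    wc <- array(0, c(dim(w)[1], dim(w)[2], 1, 1))
    wc[, , 1, 1] <- w[, , c]
    yc <- naive_conv2d(array(x[, , c], c(dim(x)[1], dim(x)[2], 1)), wc,
                       stride, if (is.null(bias)) NULL else bias[c])
    out <- if (is.null(out)) yc else
      array(c(out, yc), c(dim(yc)[1], dim(yc)[2], c))
  }
  out
}

# straight-line reference of the grouped attention equations: split into g
# groups, channel max/avg, k x k conv on the 2-channel descriptor, spatial
# softmax, residual re-weighting, concat
ref_sfsam <- function(x, W, b, g) {
  H <- dim(x)[1]; Wd <- dim(x)[2]; C <- dim(x)[3]
  n <- C / g
  k <- dim(W)[1]
  out <- array(0, dim(x))
  for (i in 1:g) {
    Fi <- x[, , ((i - 1) * n + 1):(i * n), drop = FALSE]
    fmax <- apply(Fi, c(1, 2), max)
    favg <- apply(Fi, c(1, 2), mean)
    desc <- array(c(fmax, favg), c(H, Wd, 2))
    Wi <- array(W[, , , i], c(k, k, 2, 1))
    z <- naive_conv2d(desc, Wi, 1, bias = b[i])
    ez <- exp(z - max(z))
    M <- ez / sum(ez)
    for (c in 1:n)
      out[, , (i - 1) * n + c] <- Fi[, , c] * (1 + M[, , 1])
  }
  out
}

# AUC as the normalized Mann-Whitney U statistic (pairwise comparison)
mann_whitney_auc <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}

# fetch a (possibly nested) layer of a network by name
find_layer <- function(net, name) {
  found <- NULL
  for (top in net$layers)
    seedsortnet:::walk_layers(top, function(l) if (l$name == name) found <<- l)
  found
}

# zero every parameter array of a layer subtree
zero_params <- function(layer) {
  seedsortnet:::walk_layers(layer, function(l) {
    for (nm in names(l$params))
      if (nm != "gamma") l$params[[nm]][] <- 0
  })
  invisible(layer)
}
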