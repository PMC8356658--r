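# Internal layer engine.  A layer is an environment carrying hyperparameters,
# learnable parameter arrays (`params`), their gradients (`grads`), optimizer
# state (`vel`) and a forward cache.  Composite layers hold `children`.
# Backward passes assume each leaf is visited exactly once per step.

new_layer <- function(type, name) {
  ly <- new.env(parent = emptyenv())
  ly$type <- type
  ly$name <- name
  ly$params <- list()
  ly$grads <- list()
  ly$vel <- list()
  ly$children <- list()
  class(ly) <- "ssn_layer"
  ly
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

# conv (+ optional batch norm) (+ activation) unit ---------------------------

new_cba <- function(cin, filters, kernel = 3L, stride = 1L, depthwise = FALSE,
                    activation = "relu6", use_bias = TRUE, use_bn = TRUE,
                    name = "cba") {
  if (filters <= 0) stop("conv_bn_act: filters must be positive")
  if (!kernel %in% c(1L, 3L, 7L)) stop("conv_bn_act: kernel must be 1, 3 or 7")
  if (!stride %in% c(1L, 2L)) stop("conv_bn_act: stride must be 1 or 2")
  if (!activation %in% c("relu6", "linear"))
    stop("conv_bn_act: activation must be 'relu6' or 'linear'")
  if (depthwise && filters != cin)
    stop("conv_bn_act: depthwise convolution requires filters == input channels")
  ly <- new_layer("cba", name)
  ly$cin <- as.integer(cin)
  ly$cout <- as.integer(filters)
  ly$kernel <- as.integer(kernel)
  ly$stride <- as.integer(stride)
  ly$depthwise <- depthwise
  ly$activation <- activation
  ly$use_bias <- use_bias
  ly$use_bn <- use_bn
  if (depthwise) {
    ly$params$W <- he_init(c(kernel, kernel, cin), kernel * kernel)
  } else {
    ly$params$W <- he_init(c(kernel, kernel, cin, filters),
                           kernel * kernel * cin)
  }
  if (use_bias) ly$params$b <- numeric(filters)
  if (use_bn) {
    ly$params$gamma <- rep(1, filters)
    ly$params$beta <- numeric(filters)
    ly$rmean <- numeric(filters)
    ly$rvar <- rep(1, filters)
    ly$bn_momentum <- 0.1
  }
  ly
}

cba_forward <- function(ly, x, training) {
  b <- if (ly$use_bias) ly$params$b else numeric(0)
  z <- if (ly$depthwise) .dwconv2d_fwd(x, ly$params$W, b, ly$stride)
       else .conv2d_fwd(x, ly$params$W, b, ly$stride)
  relu <- ly$activation == "relu6"
  if (ly$use_bn) {
    if (training) {
      st <- .bn_stats(z)
      ly$rmean <- (1 - ly$bn_momentum) * ly$rmean + ly$bn_momentum * st$mean
      ly$rvar <- (1 - ly$bn_momentum) * ly$rvar + ly$bn_momentum * st$var
      mu <- st$mean
      istd <- 1 / sqrt(st$var + bn_eps)
      ly$cache <- list(x = x, z = z, mu = mu, istd = istd)
    } else {
      mu <- ly$rmean
      istd <- 1 / sqrt(ly$rvar + bn_eps)
    }
    .bn_act_fwd(z, ly$params$gamma, ly$params$beta, mu, istd, relu)
  } else {
    if (training) ly$cache <- list(x = x, z = z)
    if (relu) .relu6_fwd(z) else z
  }
}

cba_backward <- function(ly, dy) {
  if (ly$use_bn) {
    bb <- .bn_act_bwd(ly$cache$z, dy, ly$params$gamma, ly$params$beta,
                      ly$cache$mu, ly$cache$istd,
                      ly$activation == "relu6", TRUE)
    ly$grads$gamma <- bb$dgamma
    ly$grads$beta <- bb$dbeta
    dy <- bb$dx
  } else if (ly$activation == "relu6") {
    dy <- relu6_bwd(ly$cache$z, dy)
  }
  cv <- if (ly$depthwise)
    .dwconv2d_bwd(ly$cache$x, ly$params$W, dy, ly$stride, ly$use_bias)
  else
    .conv2d_bwd(ly$cache$x, ly$params$W, dy, ly$stride, ly$use_bias)
  ly$grads$W <- cv$dw
  if (ly$use_bias) ly$grads$b <- cv$db
  ly$cache <- NULL
  cv$dx
}

# anti-aliased downsampling --------------------------------------------------

new_mbp <- function(blur_size = 3L, name = "maxblurpool") {
  ly <- new_layer("mbp", name)
  ly$kern <- blur_kernel(blur_size)
  ly
}

mbp_forward <- function(ly, x, training) {
  d <- dim(x)
  if (d[1] < 2 || d[2] < 2) stop("max_blur_pool: spatial dims must be >= 2")
  mp <- .maxpool2_s1_fwd(x)
  if (training) ly$cache <- list(argmax = mp$argmax, mid_dim = dim(mp$y))
  .blurpool_fwd(mp$y, ly$kern, 2L)
}

mbp_backward <- function(ly, dy) {
  dmid <- .blurpool_bwd(dy, ly$kern, ly$cache$mid_dim, 2L)
  .maxpool2_s1_bwd(dmid, ly$cache$argmax)
}

# channel concat helpers ------------------------------------------------------

cat_channels <- function(parts) Reduce(.channel_concat2, parts)

slice_channels <- function(x, from, len) .channel_slice(x, as.integer(from),
                                                        as.integer(len))

# dual-branch stem -----------------------------------------------------------

new_root <- function(cin = 3L, stem_filters = 16L, branch_filters = 56L,
                     blur_size = 3L, name = "root") {
  ly <- new_layer("root", name)
  ly$cout <- 2L * stem_filters
  ly$children <- list(
    stem = new_cba(cin, stem_filters, 3L, 1L, name = paste0(name, ".stem")),
    pool = new_mbp(blur_size, name = paste0(name, ".pool")),
    b2a = new_cba(stem_filters, branch_filters, 3L, 2L,
                  name = paste0(name, ".branch2_conv3")),
    b2b = new_cba(branch_filters, stem_filters, 1L, 1L,
                  name = paste0(name, ".branch2_conv1"))
  )
  ly
}

root_forward <- function(ly, x, training) {
  ch <- ly$children
  s <- cba_forward(ch$stem, x, training)
  p <- mbp_forward(ch$pool, s, training)
  q <- cba_forward(ch$b2b, cba_forward(ch$b2a, s, training), training)
  cat_channels(list(p, q))
}

root_backward <- function(ly, dy) {
  ch <- ly$children
  nf <- ch$stem$cout
  dp <- slice_channels(dy, 1L, nf)
  dq <- slice_channels(dy, nf + 1L, nf)
  ds <- mbp_backward(ch$pool, dp) +
    cba_backward(ch$b2a, cba_backward(ch$b2b, dq))
  cba_backward(ch$stem, ds)
}

# Shield-block ----------------------------------------------------------------

new_shield <- function(spec, name = "shield") {
  ly <- new_layer("shield", name)
  ly$spec <- spec
  ly$children <- list(
    m1 = new_cba(spec$in_channels, spec$in_channels, 3L, depthwise = TRUE,
                 name = paste0(name, ".main_dw1")),
    m2 = new_cba(spec$in_channels, spec$hidden, 1L, activation = "linear",
                 name = paste0(name, ".main_pw_reduce")),
    m3 = new_cba(spec$hidden, spec$main, 1L,
                 name = paste0(name, ".main_pw_expand")),
    m4 = new_cba(spec$main, spec$main, 3L, depthwise = TRUE,
                 activation = "linear", name = paste0(name, ".main_dw2")),
    s1 = new_cba(spec$in_channels, spec$in_channels, 3L, depthwise = TRUE,
                 name = paste0(name, ".sub_dw")),
    s2 = new_cba(spec$in_channels, spec$sub, 1L,
                 name = paste0(name, ".sub_pw"))
  )
  ly
}

shield_forward <- function(ly, x, training) {
  ch <- ly$children
  main <- cba_forward(ch$m4,
            cba_forward(ch$m3,
              cba_forward(ch$m2,
                cba_forward(ch$m1, x, training), training), training), training)
  sub <- cba_forward(ch$s2, cba_forward(ch$s1, x, training), training)
  y <- cat_channels(list(main, sub))
  if (ly$spec$use_shortcut) y <- y + x
  y
}

shield_backward <- function(ly, dy) {
  ch <- ly$children
  sp <- ly$spec
  dmain <- slice_channels(dy, 1L, sp$main)
  dsub <- slice_channels(dy, sp$main + 1L, sp$sub)
  dx <- cba_backward(ch$m1,
          cba_backward(ch$m2,
            cba_backward(ch$m3, cba_backward(ch$m4, dmain)))) +
        cba_backward(ch$s1, cba_backward(ch$s2, dsub))
  if (sp$use_shortcut) dx <- dx + dy
  dx
}

# global average pool, channel dropout, fully-connected head ------------------

new_gap <- function(name = "gap") new_layer("gap", name)

gap_forward <- function(ly, x, training) {
  d <- dim(x)
  if (training) ly$cache <- list(in_dim = d)
  xm <- matrix(x, d[1] * d[2], d[3] * d[4])
  array(colMeans(xm), dim = c(1L, 1L, d[3], d[4]))
}

gap_backward <- function(ly, dy) {
  d <- ly$cache$in_dim
  hw <- d[1] * d[2]
  array(rep(as.vector(dy) / hw, each = hw), dim = d)
}

new_dropout <- function(rate, name = "dropout") {
  ly <- new_layer("dropout", name)
  ly$rate <- rate
  ly
}

dropout_forward <- function(ly, x, training) {
  if (!training || ly$rate <= 0) return(x)
  d <- dim(x)
  keep <- matrix(stats::runif(d[3] * d[4]) >= ly$rate, d[3], d[4])
  mask <- array(rep(as.numeric(keep) / (1 - ly$rate), each = d[1] * d[2]),
                dim = d)
  ly$cache <- list(mask = mask)
  x * mask
}

dropout_backward <- function(ly, dy) {
  if (is.null(ly$cache$mask)) return(dy)
  dy * ly$cache$mask
}

new_fc <- function(cin, cout, name = "fc") {
  ly <- new_layer("fc", name)
  ly$cin <- as.integer(cin)
  ly$cout <- as.integer(cout)
  ly$params$W <- array(stats::rnorm(cin * cout, sd = sqrt(1 / cin)),
                       dim = c(cin, cout))
  ly$params$b <- numeric(cout)
  ly
}

fc_forward <- function(ly, x, training) {
  d <- dim(x)
  xm <- matrix(x, d[3], d[4])  # expects 1 x 1 x C x N
  if (training) ly$cache <- list(xm = xm)
  t(crossprod(ly$params$W, xm) + ly$params$b)  # N x cout
}

fc_backward <- function(ly, dy) {
  # dy: N x cout
  dym <- t(dy)  # cout x N
  ly$grads$W <- ly$cache$xm %*% dy            # cin x cout
  ly$grads$b <- rowSums(dym)
  dxm <- ly$params$W %*% dym                  # cin x N
  array(dxm, dim = c(1L, 1L, nrow(dxm), ncol(dxm)))
}

# dispatch --------------------------------------------------------------------

ly_forward <- function(ly, x, training = FALSE) {
  switch(ly$type,
    cba = cba_forward(ly, x, training),
    mbp = mbp_forward(ly, x, training),
    root = root_forward(ly, x, training),
    shield = shield_forward(ly, x, training),
    sfsam = sfsam_layer_forward(ly, x, training),
    gap = gap_forward(ly, x, training),
    dropout = dropout_forward(ly, x, training),
    fc = fc_forward(ly, x, training),
    stop("unknown layer type: ", ly$type)
  )
}

ly_backward <- function(ly, dy) {
  switch(ly$type,
    cba = cba_backward(ly, dy),
    mbp = mbp_backward(ly, dy),
    root = root_backward(ly, dy),
    shield = shield_backward(ly, dy),
    sfsam = sfsam_layer_backward(ly, dy),
    gap = gap_backward(ly, dy),
    dropout = dropout_backward(ly, dy),
    fc = fc_backward(ly, dy),
    stop("unknown layer type: ", ly$type)
  )
}

# walk every layer (composite and leaf) depth-first
walk_layers <- function(ly, fn) {
  fn(ly)
  for (ch in ly$children) walk_layers(ch, fn)
  invisible(NULL)
}

# number of learnable scalars in a layer subtree
layer_n_params <- function(ly) {
  n <- 0
  walk_layers(ly, function(l) n <<- n + sum(vapply(l$params, length, 0)))
  n
}

sgd_update_layer <- function(ly, lr, momentum, weight_decay) {
  walk_layers(ly, function(l) {
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      if (is.null(g)) next
      g <- g + weight_decay * l$params[[nm]]
      v <- l$vel[[nm]]
      if (is.null(v)) v <- 0
      v <- momentum * v + g
      l$vel[[nm]] <- v
      l$params[[nm]] <- l$params[[nm]] - lr * v
    }
  })
}
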