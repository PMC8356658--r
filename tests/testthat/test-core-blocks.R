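test_that("conv_bn_act matches a direct-summation convolution oracle", {
  set.seed(101)
  cases <- list(
    list(kernel = 3, stride = 1, depthwise = FALSE, filters = 5),
    list(kernel = 3, stride = 2, depthwise = FALSE, filters = 4),
    list(kernel = 1, stride = 1, depthwise = FALSE, filters = 7),
    list(kernel = 7, stride = 1, depthwise = FALSE, filters = 2),
    list(kernel = 3, stride = 1, depthwise = TRUE, filters = 3),
    list(kernel = 3, stride = 2, depthwise = TRUE, filters = 3)
  )
  for (cs in cases) {
    x <- rand_feature(8, 6, 3)
    y <- conv_bn_act(x, cs$filters, cs$kernel, cs$stride,
                     depthwise = cs$depthwise, activation = "linear",
                     use_bn = FALSE)
    ly <- attr(y, "layer")
    ref <- if (cs$depthwise)
      naive_dwconv2d(x, ly$params$W, cs$stride, ly$params$b)
    else
      naive_conv2d(x, ly$params$W, cs$stride, ly$params$b)
    expect_equal(dim(y), dim(ref))
    expect_equal(as.vector(y), as.vector(ref), tolerance = 1e-12)
  }
})

test_that("conv_bn_act output geometry and activation clamp behave as specified", {
  set.seed(102)
  # stem geometry: 224 x 224 x 3 in, 16 3x3 filters, stride 1
  x <- rand_feature(224, 224, 3)
  y <- conv_bn_act(x, 16, 3, 1)
  expect_equal(dim(y), c(224, 224, 16))
  # relu6 clamps to [0, 6]: identity conv + large bias, no normalization
  x1 <- array(abs(rnorm(25)), c(5, 5, 1))
  ly <- seedsortnet:::new_cba(1, 1, 1, depthwise = TRUE, use_bn = FALSE)
  ly$params$W[] <- 1
  ly$params$b[] <- 10
  y1 <- conv_bn_act(x1, 1, 1, depthwise = TRUE, layer = ly)
  expect_true(all(y1 <= 6) && all(y1 >= 0))
  expect_true(all(y1 == 6))  # all inputs pushed past the clamp
})

test_that("learnable-parameter accounting of the conv unit is exact", {
  # 1x1 conv 4 -> 8 without bias plus its batch-norm affine pair: 32 + 16
  x <- rand_feature(4, 4, 4)
  y <- conv_bn_act(x, 8, 1, use_bias = FALSE)
  expect_equal(seedsortnet:::layer_n_params(attr(y, "layer")), 48)
  # with bias: + 8
  y2 <- conv_bn_act(x, 8, 1, use_bias = TRUE)
  expect_equal(seedsortnet:::layer_n_params(attr(y2, "layer")), 56)
})

test_that("conv_bn_act rejects invalid configurations", {
  x <- rand_feature(4, 4, 3)
  expect_error(conv_bn_act(x, 0, 3), "positive")
  expect_error(conv_bn_act(x, 5, 3, depthwise = TRUE), "depthwise")
  expect_error(conv_bn_act(x, 4, 5), "kernel")
})

test_that("root module halves resolution and doubles the stem width", {
  set.seed(103)
  x <- rand_feature(224, 224, 3)
  y <- root_module(x)
  expect_equal(dim(y), c(112, 112, 32))
  expect_error(root_module(rand_feature(16, 16, 4)), "3-channel")
  expect_error(root_module(rand_feature(15, 16, 3)), "even")
})

test_that("root branch 1 propagates constants away from the padded border", {
  # the stem convolution of a constant input is constant except where the
  # zero padding reaches; the dense max and normalized blur of a constant
  # are that constant, so the interior of branch 1 must stay constant
  x <- array(0.5, c(16, 16, 3))
  y <- root_module(x)
  b1 <- y[2:7, 2:7, 1:16]
  for (c in 1:16) expect_lt(max(b1[, , c]) - min(b1[, , c]), 1e-10)
})

test_that("root stem parameter total matches the layer-by-layer hand count", {
  # stem 3x3 3->16 (432 + 16b + 32bn) + branch-2 3x3 16->56 (8064 + 56 + 112)
  # + 1x1 56->16 (896 + 16 + 32) = 9656
  set.seed(104)
  y <- root_module(rand_feature(16, 16, 3))
  expect_equal(seedsortnet:::layer_n_params(attr(y, "layer")), 9656)
})

test_that("shield block channel bookkeeping is exact for every stage width", {
  sp <- shield_block_spec(192, 192, 6, use_shortcut = TRUE)
  expect_equal(sp$hidden, 32)
  expect_equal(sp$main, 160)
  expect_equal(sp$sub, 32)
  for (C in c(64, 128, 192, 256)) {
    sp <- shield_block_spec(C, C, 6, use_shortcut = TRUE)
    expect_equal(sp$main + sp$sub, C)
    expect_equal(sp$sub, C %/% 6)
  }
  # channel-expanding first blocks of the four stages
  firsts <- list(c(32, 64), c(64, 128), c(128, 192), c(192, 256))
  for (f in firsts) {
    sp <- shield_block_spec(f[1], f[2], 2)
    expect_false(sp$use_shortcut)
    expect_equal(sp$hidden, round(f[2] / 2))
    expect_equal(sp$main + sp$sub, f[2])
  }
  expect_error(shield_block_spec(32, 64, 2, use_shortcut = TRUE), "shortcut")
  expect_error(shield_block_spec(4, 4, 6), "sub-branch")
})

test_that("a shortcut shield block with zeroed branches is the identity", {
  set.seed(105)
  sp <- shield_block_spec(12, 12, 6, use_shortcut = TRUE)
  ly <- seedsortnet:::new_shield(sp)
  zero_params(ly)
  x <- rand_feature(7, 7, 12)
  y <- shield_block(x, sp, layer = ly)
  expect_identical(as.vector(y), as.vector(x))
})

test_that("shield block output shape follows the spec", {
  set.seed(106)
  x <- rand_feature(9, 9, 32)
  y <- shield_block(x, shield_block_spec(32, 64, 2))
  expect_equal(dim(y), c(9, 9, 64))
  expect_error(shield_block(rand_feature(9, 9, 16),
                            shield_block_spec(32, 64, 2)), "channels")
})

test_that("max blur pool preserves constants and halves spatial dims", {
  x <- array(3.7, c(10, 10, 2))
  y <- max_blur_pool(x)
  expect_equal(dim(y), c(5, 5, 2))
  expect_equal(as.vector(y), rep(3.7, 50), tolerance = 1e-12)
  # odd input: ceil(H/2)
  y2 <- max_blur_pool(rand_feature(7, 9, 1))
  expect_equal(dim(y2), c(4, 5, 1))
  expect_error(max_blur_pool(array(1, c(1, 4, 1))), "spatial")
  # 112 x 112 x 64 -> 56 x 56 x 64 stage geometry
  y3 <- max_blur_pool(rand_feature(112, 112, 4))
  expect_equal(dim(y3), c(56, 56, 4))
})

test_that("blur kernel is a normalized nonnegative low-pass filter", {
  k <- seedsortnet:::blur_kernel(3)
  expect_equal(sum(k), 1)
  expect_true(all(k >= 0))
  expect_equal(as.vector(k), as.vector(outer(c(1, 2, 1), c(1, 2, 1)) / 16))
})

test_that("MaxBlurPool is more shift-consistent than plain MaxPool", {
  set.seed(107)
  shift1 <- function(x) {
    # 1-pixel downward shift with edge replication
    x[c(1, seq_len(dim(x)[1] - 1)), , , drop = FALSE]
  }
  dist_after <- function(op, x) {
    a <- op(x)
    b <- op(shift1(x))
    crop <- 2:(dim(a)[1] - 1)
    mean(abs(a[crop, crop, , drop = FALSE] - b[crop, crop, , drop = FALSE]))
  }
  d_blur <- d_max <- numeric(100)
  for (i in 1:100) {
    x <- rand_feature(16, 16, 1)
    d_blur[i] <- dist_after(max_blur_pool, x)
    d_max[i] <- dist_after(max_pool2, x)
  }
  expect_lt(mean(d_blur), mean(d_max))
  expect_gt(mean(d_max) / mean(d_blur), 1.2)  # clear margin, not a tie
})

test_that("block backward passes agree with numerical gradients", {
  set.seed(108)
  num_grad <- function(fwd, ly, pname, idx, eps = 1e-6) {
    th <- ly$params[[pname]]
    ly$params[[pname]][idx] <- th[idx] + eps
    lp <- fwd()
    ly$params[[pname]][idx] <- th[idx] - eps
    lm <- fwd()
    ly$params[[pname]][idx] <- th[idx]
    (lp - lm) / (2 * eps)
  }
  # conv + bn (linear activation keeps the loss smooth)
  x <- rand_feature(6, 6, 3, n = 2)
  ly <- seedsortnet:::new_cba(3, 4, 3, activation = "linear")
  loss <- function() {
    y <- seedsortnet:::cba_forward(ly, x, training = TRUE)
    sum(y * seq_along(y)) / length(y)
  }
  l0 <- loss()
  dy <- array(seq_len(6 * 6 * 4 * 2), c(6, 6, 4, 2)) / (6 * 6 * 4 * 2)
  seedsortnet:::cba_backward(ly, dy)
  for (pp in list(c("W", 7), c("b", 2), c("gamma", 3), c("beta", 1))) {
    idx <- as.integer(pp[2])
    g_num <- num_grad(loss, ly, pp[1], idx)
    expect_equal(ly$grads[[pp[1]]][idx], g_num, tolerance = 1e-5,
                 label = paste("cba grad", pp[1]))
  }
  # depthwise path
  lyd <- seedsortnet:::new_cba(3, 3, 3, depthwise = TRUE, activation = "linear")
  lossd <- function() {
    y <- seedsortnet:::cba_forward(lyd, x, training = TRUE)
    sum(y^2) / length(y)
  }
  y <- seedsortnet:::cba_forward(lyd, x, training = TRUE)
  seedsortnet:::cba_backward(lyd, 2 * y / length(y))
  expect_equal(lyd$grads$W[5], num_grad(lossd, lyd, "W", 5), tolerance = 1e-5)
  # max blur pool input gradient
  xm <- rand_feature(8, 8, 2, n = 1)
  mb <- seedsortnet:::new_mbp()
  lossm <- function(xx) {
    y <- seedsortnet:::mbp_forward(mb, xx, training = TRUE)
    sum(y^3)
  }
  y <- seedsortnet:::mbp_forward(mb, xm, training = TRUE)
  dx <- seedsortnet:::mbp_backward(mb, 3 * y^2)
  i <- 23
  eps <- 1e-6
  xp <- xm; xp[i] <- xp[i] + eps
  xn <- xm; xn[i] <- xn[i] - eps
  expect_equal(dx[i], (lossm(xp) - lossm(xn)) / (2 * eps), tolerance = 1e-5)
})
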