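test_that("group splitting is an exact order-preserving partition", {
  set.seed(201)
  f <- rand_feature(5, 5, 64)
  gs <- split_groups(f, 4)
  expect_length(gs, 4)
  for (g in gs) expect_equal(dim(g), c(5, 5, 16))
  recon <- array(unlist(gs), dim = dim(f))
  expect_identical(as.vector(recon), as.vector(f))
  # g = 1 is the identity partition
  expect_identical(split_groups(f, 1)[[1]], f)
  expect_error(split_groups(f, 5), "not divisible")
})

test_that("channel pooling computes per-position max and mean", {
  # 2 x 1 x 2 enumeration: channels (1,3) at position a, (2,2) at b
  fi <- array(c(1, 2, 3, 2), c(2, 1, 2))
  d <- channel_pool(fi)
  expect_equal(as.vector(d[, , 1]), c(3, 2))  # max
  expect_equal(as.vector(d[, , 2]), c(2, 2))  # mean
  # channel-constant input: both descriptor channels equal that value
  fc <- array(0.7, c(3, 4, 5))
  dc <- channel_pool(fc)
  expect_true(all(dc == 0.7))
  # single channel: both descriptors equal the input
  f1 <- rand_feature(4, 4, 1, seed = 202)
  d1 <- channel_pool(f1)
  expect_equal(as.vector(d1[, , 1]), as.vector(f1))
  expect_equal(as.vector(d1[, , 2]), as.vector(f1))
})

test_that("attention maps are spatial probability distributions", {
  set.seed(203)
  cfg <- attention_config()
  d <- rand_feature(6, 7, 2)
  m <- attention_map(d, cfg)
  expect_equal(dim(m), c(6, 7))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(sum(m), 1, tolerance = 1e-12)
  # a constant pre-gate logit map (zero filter, bias only) must gate to
  # the uniform distribution 1/(H*W)
  wz <- list(W = array(0, c(7, 7, 2, 1)), b = 0.5)
  mu <- attention_map(array(0.3, c(5, 4, 2)), cfg, weights = wz)
  expect_equal(as.vector(mu), rep(1 / 20, 20), tolerance = 1e-12)
  expect_error(attention_config(kernel = 6), "odd")
  expect_error(attention_map(rand_feature(4, 4, 3), cfg), "2 channels")
})

test_that("per-group attention filter bank has 2k^2 + 1 parameters", {
  set.seed(204)
  f <- rand_feature(6, 6, 8)
  y <- sfsam_forward(f, attention_config(groups = 4))
  ly <- attr(y, "layer")
  expect_equal(seedsortnet:::layer_n_params(ly), 4 * (2 * 49 + 1))
  expect_equal(4 * (2 * 49 + 1), 396)
})

test_that("sfsam_forward preserves shape and matches the straight-line reference", {
  for (case in list(c(6, 6, 8, 1), c(5, 7, 12, 4), c(4, 4, 16, 2),
                    c(3, 3, 12, 6))) {
    set.seed(205 + case[4])
    f <- rand_feature(case[1], case[2], case[3])
    cfg <- attention_config(groups = case[4])
    y <- sfsam_forward(f, cfg)
    expect_equal(dim(y), dim(f))
    ly <- attr(y, "layer")
    ref <- ref_sfsam(f, ly$params$W, ly$params$b, case[4])
    expect_equal(as.vector(y), as.vector(ref), tolerance = 1e-10)
  }
})

test_that("gating bounds hold: maps in [0,1] summing to 1 per group", {
  set.seed(206)
  f <- rand_feature(6, 6, 16, n = 3)
  ly <- seedsortnet:::new_sfsam(16, attention_config(groups = 4))
  ly$params$W[] <- rnorm(length(ly$params$W), sd = 0.5)
  invisible(seedsortnet:::sfsam_layer_forward(ly, f, training = TRUE))
  m <- ly$cache$m  # H x W x g x N
  expect_true(all(m >= 0 & m <= 1))
  sums <- apply(m, c(3, 4), sum)
  expect_equal(as.vector(sums), rep(1, 4 * 3), tolerance = 1e-10)
})

test_that("zero attention maps reduce the re-weighting to the identity", {
  set.seed(207)
  f <- rand_feature(5, 5, 8)
  y <- apply_attention(f, array(0, c(5, 5, 4)))
  expect_identical(as.vector(y), as.vector(f))
})

test_that("residual floor: nonnegative inputs are never attenuated", {
  set.seed(208)
  f <- array(abs(rnorm(6 * 6 * 8)), c(6, 6, 8))
  y <- sfsam_forward(f, attention_config(groups = 2))
  expect_true(all(y >= f - 1e-14))
})

test_that("indivisible channel counts are rejected naming the site", {
  expect_error(
    seedsortnet:::new_sfsam(64, attention_config(groups = 5),
                            name = "stage03_sfsam"),
    "stage03_sfsam.*not divisible")
})

test_that("sfsam backward agrees with numerical gradients", {
  set.seed(209)
  f <- rand_feature(5, 5, 8, n = 2)
  ly <- seedsortnet:::new_sfsam(8, attention_config(groups = 2))
  ly$params$W[] <- rnorm(length(ly$params$W), sd = 0.3)
  loss <- function() {
    y <- seedsortnet:::sfsam_layer_forward(ly, f, training = TRUE)
    sum(y * seq_along(y)) / length(y)
  }
  y <- seedsortnet:::sfsam_layer_forward(ly, f, training = TRUE)
  dy <- array(seq_along(y), dim(y)) / length(y)
  dx <- seedsortnet:::sfsam_layer_backward(ly, dy)
  eps <- 1e-6
  for (idx in c(3, 50, 120)) {
    th <- ly$params$W
    ly$params$W[idx] <- th[idx] + eps; lp <- loss()
    ly$params$W[idx] <- th[idx] - eps; lm <- loss()
    ly$params$W[idx] <- th[idx]
    expect_equal(ly$grads$W[idx], (lp - lm) / (2 * eps), tolerance = 1e-4)
  }
  fp <- f; fp[77] <- fp[77] + eps
  fm <- f; fm[77] <- fm[77] - eps
  loss_x <- function(xx) {
    yy <- seedsortnet:::sfsam_layer_forward(ly, xx, training = TRUE)
    sum(yy * seq_along(yy)) / length(yy)
  }
  expect_equal(dx[77], (loss_x(fp) - loss_x(fm)) / (2 * eps),
               tolerance = 1e-4)
})
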