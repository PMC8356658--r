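test_that("generation is a pure function of its spec", {
  spec <- synthetic_spec(n_per_class = 5, rng_seed = 42)
  a <- generate_dataset(spec)
  b <- generate_dataset(spec)
  expect_identical(a, b)
  # a different seed gives different pixels
  c <- generate_dataset(synthetic_spec(n_per_class = 5, rng_seed = 43))
  expect_false(identical(a$images, c$images))
  # generation must not disturb the caller's RNG stream
  set.seed(1); r1 <- runif(1)
  set.seed(1); invisible(generate_dataset(spec)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("generated sets are balanced, sized and bounded as specified", {
  set <- generate_dataset(synthetic_spec(n_per_class = 7, image_size = 48))
  expect_length(set$images, 14)
  expect_equal(sum(set$labels == 1), 7)
  expect_equal(sum(set$labels == 0), 7)
  for (im in set$images) {
    expect_equal(dim(im), c(48, 48, 3))
    expect_true(all(im >= 0 & im <= 1))
  }
  # noisy pixels are clipped back into [0, 1]
  noisy <- generate_dataset(synthetic_spec(n_per_class = 3, noise_sd = 0.5))
  for (im in noisy$images) expect_true(all(im >= 0 & im <= 1))
  expect_error(synthetic_spec(n_per_class = 0), "n_per_class")
  expect_error(synthetic_spec(image_size = 16), "image_size")
})

test_that("the x4 augmentation is exact and label-preserving", {
  set <- generate_dataset(synthetic_spec(n_per_class = 4, rng_seed = 5))
  aug <- augment_x4(set)
  expect_length(aug$images, 32)  # 4 per class x 2 classes x 4 views
  expect_equal(aug$labels, rep(set$labels, 4))
  # horizontal flip is an involution
  hflip <- function(im) im[, rev(seq_len(dim(im)[2])), , drop = FALSE]
  expect_identical(hflip(hflip(set$images[[1]])), set$images[[1]])
  # the flipped copies really are the flips of the originals
  expect_equal(aug$images[[9]], hflip(set$images[[1]]))
  # rotating the rotation copy three more times restores the original
  rot90 <- function(im) aperm(im, c(2, 1, 3))[rev(seq_len(dim(im)[2])), , ,
                                              drop = FALSE]
  r <- set$images[[2]]
  for (i in 1:4) r <- rot90(r)
  expect_equal(r, set$images[[2]], tolerance = 1e-15)
})

test_that("the stratified split is seeded, disjoint and exhaustive", {
  set <- generate_dataset(synthetic_spec(n_per_class = 50, rng_seed = 6))
  sp <- train_test_split(set, 0.75)
  expect_length(sp$train$labels, 75)
  expect_length(sp$test$labels, 25)
  # per-class balance within one image of exact
  expect_lte(abs(sum(sp$train$labels == 1) - 37.5), 0.5)
  expect_lte(abs(sum(sp$test$labels == 1) - 12.5), 0.5)
  # union of the splits is the input set
  idx <- attr(sp$train, "train_idx")
  expect_length(c(idx, setdiff(seq_len(100), idx)), 100)
  all_imgs <- c(sp$train$images, sp$test$images)
  expect_setequal(vapply(all_imgs, function(i) sum(i), 0),
                  vapply(set$images, function(i) sum(i), 0))
  # same seed, same split
  sp2 <- train_test_split(set, 0.75)
  expect_identical(attr(sp2$train, "train_idx"), idx)
  expect_error(train_test_split(set, 1.2), "train_fraction")
})

test_that("a component-count rule separates the noiseless classes", {
  set <- generate_dataset(synthetic_spec(n_per_class = 100, noise_sd = 0,
                                         rng_seed = 7))
  acc <- mean(baseline_component_rule(set) == set$labels)
  expect_gt(acc, 0.9)
})

test_that("increasing noise monotonically degrades the baseline rule", {
  acc_at <- function(noise) {
    mean(sapply(1:3, function(s) {
      set <- generate_dataset(synthetic_spec(n_per_class = 20,
                                             noise_sd = noise, rng_seed = s))
      mean(baseline_component_rule(set) == set$labels)
    }))
  }
  accs <- vapply(c(0, 0.15, 0.25), acc_at, 0)
  expect_true(all(diff(accs) < 0))
})

test_that("datasets round-trip through the PNG + manifest layout", {
  set <- generate_dataset(synthetic_spec(n_per_class = 3, rng_seed = 8))
  dir <- tempfile("ds")
  manifest <- write_dataset(set, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(nrow(manifest), 6)
  back <- read_dataset(dir)
  expect_equal(back$labels, set$labels)
  # 8-bit quantization bounds the round-trip error
  err <- max(mapply(function(a, b) max(abs(a - b)), set$images, back$images))
  expect_lt(err, 1 / 255)
  unlink(dir, recursive = TRUE)
})

test_that("resizing into a network batch keeps scale and layout", {
  set <- generate_dataset(synthetic_spec(n_per_class = 2, rng_seed = 9))
  x <- as_input_batch(set, 64)
  expect_equal(dim(x), c(64, 64, 3, 4))
  expect_true(all(x >= 0 & x <= 1))
  # native-size request is a plain stack
  x100 <- as_input_batch(set, 100)
  expect_equal(as.vector(x100[, , , 1]), as.vector(set$images[[1]]))
})
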