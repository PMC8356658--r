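# Synthetic two-class seed-image generator.
#
# Emulates single-object-versus-clutter RGB sorting images of ~100x100 px:
# a "normal" image holds one centered, striped, seed-toned ellipse on a dark
# background; an "abnormal" image holds clutter (several small seeds /
# impurities), a broken seed (two separated fragments), or a stone-like
# irregular polygon with debris specks.  Every abnormal composition contains
# at least two connected components, so a simple component-count rule can
# serve as an independent check of separability.  The whole module is a
# pure function of its spec (seeded RNG).

#' Synthetic dataset specification
#'
#' @param n_per_class Images per class (classes are balanced).
#' @param image_size Side length in pixels (default 100).
#' @param noise_sd Additive Gaussian pixel noise SD on the 0-1 scale
#'   (default 0.02; pixels are clipped back to `[0, 1]`).
#' @param clutter_rate Fraction of abnormal images drawn as multi-seed
#'   clutter; the rest split evenly between broken seeds and
#'   stone-with-debris compositions (default 0.5).
#' @param rng_seed Integer seed; the dataset is fully determined by it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = 50L, image_size = 100L,
                           noise_sd = 0.02, clutter_rate = 0.5,
                           rng_seed = 1L) {
  if (n_per_class < 1) stop("synthetic_spec: n_per_class must be >= 1")
  if (image_size < 32) stop("synthetic_spec: image_size must be >= 32")
  if (clutter_rate < 0 || clutter_rate > 1)
    stop("synthetic_spec: clutter_rate must be in [0, 1]")
  structure(list(n_per_class = as.integer(n_per_class),
                 image_size = as.integer(image_size),
                 noise_sd = noise_sd, clutter_rate = clutter_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

# -- drawing helpers (all operate on s x s coordinate grids) -----------------

seed_tone <- function() {
  base <- c(0.58, 0.44, 0.26)
  base * stats::runif(1, 0.85, 1.1) + stats::rnorm(3, sd = 0.02)
}

# mask + per-pixel intensity of a striped ellipse
ellipse_patch <- function(s, cx, cy, a, b, theta, stripe_freq) {
  xs <- matrix(rep(seq_len(s), each = s), s, s)   # column index
  ys <- matrix(rep(seq_len(s), times = s), s, s)  # row index
  dx <- xs - cx; dy <- ys - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  rad <- (u / a)^2 + (v / b)^2
  mask <- rad <= 1
  shading <- 1 - 0.25 * rad                       # center brighter than rim
  stripes <- 1 + 0.15 * sin(2 * pi * stripe_freq * v / (2 * b))
  list(mask = mask, intensity = shading * stripes)
}

polygon_patch <- function(s, cx, cy, radius, nvert) {
  ang <- sort(stats::runif(nvert, 0, 2 * pi))
  rad <- radius * stats::runif(nvert, 0.55, 1)
  px <- cx + rad * cos(ang)
  py <- cy + rad * sin(ang)
  xs <- matrix(rep(seq_len(s), each = s), s, s)
  ys <- matrix(rep(seq_len(s), times = s), s, s)
  # even-odd ray casting, vectorized over pixels
  inside <- matrix(FALSE, s, s)
  j <- nvert
  for (i in seq_len(nvert)) {
    crosses <- ((py[i] > ys) != (py[j] > ys)) &
      (xs < (px[j] - px[i]) * (ys - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  list(mask = inside, intensity = matrix(1, s, s))
}

paint <- function(img, patch, tone) {
  for (ch in 1:3) {
    plane <- img[, , ch]
    val <- pmax(patch$intensity * tone[ch], 0)
    plane[patch$mask] <- val[patch$mask]
    img[, , ch] <- plane
  }
  img
}

background <- function(s) {
  g <- 0.06 + 0.04 * matrix(rep(seq_len(s) / s, each = s), s, s)
  img <- array(0, dim = c(s, s, 3))
  for (ch in 1:3) img[, , ch] <- g * c(1.0, 0.95, 0.9)[ch]
  img
}

draw_normal <- function(s) {
  img <- background(s)
  cx <- s / 2 + stats::runif(1, -0.05, 0.05) * s
  cy <- s / 2 + stats::runif(1, -0.05, 0.05) * s
  a <- stats::runif(1, 0.24, 0.33) * s
  b <- a * stats::runif(1, 0.5, 0.75)
  patch <- ellipse_patch(s, cx, cy, a, b, stats::runif(1, 0, pi),
                         stripe_freq = stats::runif(1, 4, 8))
  paint(img, patch, seed_tone())
}

draw_abnormal <- function(s, clutter_rate) {
  img <- background(s)
  u <- stats::runif(1)
  if (u < clutter_rate) {
    # clutter: several small seeds / impurities, well separated
    k <- sample(2:4, 1)
    centers <- list(c(0.28, 0.28), c(0.72, 0.72), c(0.3, 0.74), c(0.74, 0.3))
    for (i in seq_len(k)) {
      ctr <- centers[[i]] * s + stats::runif(2, -0.04, 0.04) * s
      a <- stats::runif(1, 0.09, 0.14) * s
      patch <- ellipse_patch(s, ctr[1], ctr[2], a,
                             a * stats::runif(1, 0.5, 0.8),
                             stats::runif(1, 0, pi), stats::runif(1, 3, 6))
      img <- paint(img, patch, seed_tone())
    }
  } else if (u < clutter_rate + (1 - clutter_rate) / 2) {
    # broken seed: two fragments of one ellipse pulled apart
    theta <- stats::runif(1, 0, pi)
    a <- stats::runif(1, 0.2, 0.28) * s
    b <- a * stats::runif(1, 0.5, 0.7)
    gap <- stats::runif(1, 0.1, 0.16) * s
    off <- c(cos(theta), sin(theta)) * (a / 2 + gap / 2)
    tone <- seed_tone()
    for (sgn in c(-1, 1)) {
      ctr <- c(s / 2, s / 2) + sgn * off
      patch <- ellipse_patch(s, ctr[1], ctr[2], a * 0.45, b,
                             theta, stats::runif(1, 3, 6))
      img <- paint(img, patch, tone)
    }
  } else {
    # stone-like irregular polygon plus debris specks
    patch <- polygon_patch(s, s * stats::runif(1, 0.4, 0.6),
                           s * stats::runif(1, 0.4, 0.6),
                           s * stats::runif(1, 0.16, 0.24), sample(5:8, 1))
    gray <- stats::runif(1, 0.4, 0.6)
    img <- paint(img, patch, gray * c(1, 0.98, 0.95))
    for (i in 1:2) {
      ctr <- stats::runif(2, 0.12, 0.88) * s
      a <- stats::runif(1, 0.03, 0.05) * s
      speck <- ellipse_patch(s, ctr[1], ctr[2], a, a * 0.8,
                             stats::runif(1, 0, pi), 1)
      img <- paint(img, speck, seed_tone())
    }
  }
  img
}

#' Generate a labeled synthetic seed-image set
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `labeled_image_set`: a list with `images`
#'   (list of `image_size x image_size x 3` arrays in `[0, 1]`), `labels`
#'   (integer, 1 = normal, 0 = abnormal) and `spec` (provenance).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$rng_seed, {
    s <- spec$image_size
    n <- spec$n_per_class
    images <- vector("list", 2L * n)
    labels <- integer(2L * n)
    for (i in seq_len(n)) {
      images[[i]] <- draw_normal(s)
      labels[i] <- 1L
    }
    for (i in seq_len(n)) {
      images[[n + i]] <- draw_abnormal(s, spec$clutter_rate)
      labels[n + i] <- 0L
    }
    if (spec$noise_sd > 0) {
      images <- lapply(images, function(im) {
        im <- im + array(stats::rnorm(length(im), sd = spec$noise_sd), dim(im))
        im[im < 0] <- 0; im[im > 1] <- 1
        im
      })
    }
    structure(list(images = images, labels = labels, spec = spec),
              class = "labeled_image_set")
  })
}

#' Four-fold geometric augmentation
#'
#' Expands the set by a factor of 4: original, horizontal flip, vertical
#' flip and a 90-degree rotation; labels are copied.
#'
#' @param set A `labeled_image_set`.
#' @return The augmented `labeled_image_set` (4x the images).
#' @export
augment_x4 <- function(set) {
  if (length(set$images) == 0) stop("augment_x4: empty image set")
  hflip <- function(im) im[, rev(seq_len(dim(im)[2])), , drop = FALSE]
  vflip <- function(im) im[rev(seq_len(dim(im)[1])), , , drop = FALSE]
  rot90 <- function(im) aperm(im, c(2, 1, 3))[rev(seq_len(dim(im)[2])), , ,
                                              drop = FALSE]
  images <- c(set$images,
              lapply(set$images, hflip),
              lapply(set$images, vflip),
              lapply(set$images, rot90))
  structure(list(images = images, labels = rep(set$labels, 4L),
                 spec = set$spec),
            class = "labeled_image_set")
}

#' Stratified train/test split
#'
#' Draws a seeded stratified random split: the train partition holds
#' `round(N * train_fraction)` images, allocated per class by largest
#' remainder so the partitions stay as balanced as the fraction allows,
#' and the two partitions are disjoint and exhaustive.
#'
#' @param set A `labeled_image_set`.
#' @param train_fraction Fraction of images assigned to the train split.
#' @param rng_seed Seed for the split (default: the set's own seed + 1).
#' @return A list with elements `train` and `test`, both
#'   `labeled_image_set`s, plus `train_idx` attribute on `train`.
#' @export
train_test_split <- function(set, train_fraction = 0.75,
                             rng_seed = set$spec$rng_seed + 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_test_split: train_fraction must be in (0, 1)")
  labels <- set$labels
  classes <- sort(unique(labels))
  if (any(table(labels) < 2))
    stop("train_test_split: every class needs at least 2 samples")
  n_total <- length(labels)
  n_train <- round(n_total * train_fraction)
  per_class <- table(labels)[as.character(classes)]
  exact <- as.numeric(per_class) * train_fraction
  base <- floor(exact)
  rem <- n_train - sum(base)
  if (rem > 0) {
    order_frac <- order(exact - base, decreasing = TRUE)
    base[order_frac[seq_len(rem)]] <- base[order_frac[seq_len(rem)]] + 1
  }
  idx <- with_seed(rng_seed, {
    unlist(lapply(seq_along(classes), function(ci) {
      pool <- which(labels == classes[ci])
      sample(pool, base[ci])
    }))
  })
  idx <- sort(idx)
  subset_set <- function(i) {
    structure(list(images = set$images[i], labels = set$labels[i],
                   spec = set$spec),
              class = "labeled_image_set")
  }
  train <- subset_set(idx)
  attr(train, "train_idx") <- idx
  list(train = train, test = subset_set(setdiff(seq_len(n_total), idx)))
}

#' Resize a set into a network input batch
#'
#' Bilinearly resizes every image to `size x size` (mirroring the
#' resize-to-input preprocessing used at training time) and stacks them
#' into an `size x size x 3 x N` array.
#'
#' @param set A `labeled_image_set`.
#' @param size Target side length.
#' @return A numeric array `size x size x 3 x N`.
#' @export
as_input_batch <- function(set, size) {
  n <- length(set$images)
  out <- array(0, dim = c(size, size, 3L, n))
  for (i in seq_len(n)) {
    im <- set$images[[i]]
    if (dim(im)[1] != size) {
      im <- EBImage::resize(EBImage::Image(im, colormode = "Color"),
                            w = size, h = size)
      im <- as.array(im)
    }
    out[, , , i] <- im
  }
  out
}

#' Component-count baseline rule
#'
#' A deliberately simple reference classifier: threshold the gray image,
#' label connected components, and call the image "normal" when exactly one
#' component remains.  Used to check that the generated classes are
#' separable without a network.
#'
#' @param set A `labeled_image_set`.
#' @param threshold Gray threshold on the 0-1 scale (default 0.18, between
#'   the dark background and the seed tones).
#' @param min_area Components smaller than this many pixels are ignored
#'   (default 10).
#' @return Integer predictions (1 = normal, 0 = abnormal).
#' @export
baseline_component_rule <- function(set, threshold = 0.18, min_area = 10) {
  vapply(set$images, function(im) {
    gray <- (im[, , 1] + im[, , 2] + im[, , 3]) / 3
    bw <- EBImage::bwlabel(1 * (gray > threshold))
    sizes <- tabulate(as.integer(bw[bw > 0]))
    as.integer(sum(sizes >= min_area) == 1)
  }, integer(1))
}

# ---- PNG + CSV dataset I/O --------------------------------------------------

#' Write / read a dataset as PNG files with a CSV manifest
#'
#' Images are written to `class_0/` and `class_1/` subdirectories plus a
#' `manifest.csv` with columns `path`, `label`, `split`.  `read_dataset()`
#' accepts any directory in the same layout.
#'
#' @param set A `labeled_image_set`.
#' @param dir Target directory (created if missing).
#' @param split Optional character vector of split tags per image.
#' @return `write_dataset()` the manifest data frame (invisibly);
#'   `read_dataset()` a `labeled_image_set`.
#' @export
write_dataset <- function(set, dir, split = NULL) {
  dir.create(file.path(dir, "class_0"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "class_1"), recursive = TRUE, showWarnings = FALSE)
  n <- length(set$images)
  paths <- character(n)
  for (i in seq_len(n)) {
    paths[i] <- file.path(sprintf("class_%d", set$labels[i]),
                          sprintf("img_%05d.png", i))
    png::writePNG(set$images[[i]], file.path(dir, paths[i]))
  }
  manifest <- data.frame(path = paths, label = set$labels,
                         split = if (is.null(split)) NA_character_ else split,
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (file.exists(mf)) {
    manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  } else {
    files <- c(list.files(file.path(dir, "class_0"), full.names = FALSE),
               list.files(file.path(dir, "class_1"), full.names = FALSE))
    p0 <- list.files(file.path(dir, "class_0"))
    p1 <- list.files(file.path(dir, "class_1"))
    manifest <- data.frame(
      path = c(file.path("class_0", p0), file.path("class_1", p1)),
      label = c(rep(0L, length(p0)), rep(1L, length(p1))),
      stringsAsFactors = FALSE)
  }
  images <- lapply(manifest$path, function(p) {
    im <- png::readPNG(file.path(dir, p))
    if (length(dim(im)) == 2) im <- array(rep(im, 3), dim = c(dim(im), 3))
    im[, , 1:3, drop = FALSE]
  })
  structure(list(images = images, labels = as.integer(manifest$label),
                 spec = NULL),
            class = "labeled_image_set")
}
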