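# Network assembly: the 15-stage plan, width-multiplier scaling, and the
# full network builder (Root stem -> 15 Shield-blocks in 4 stages, each
# stage followed by an SFSAM attention site and a MaxBlurPool downsampler ->
# global average pool -> channel dropout -> fully-connected head).

#' The default 15-stage network plan
#'
#' Stage layout (input 224): Root -> 32 channels at 112; Shield x2 -> 64;
#' SFSAM; pool; Shield x4 -> 128; SFSAM; pool; Shield x5 -> 192; SFSAM;
#' pool; Shield x4 -> 256; SFSAM; pool; global average pool; dropout +
#' fully-connected head.  The channel-expanding first Shield-block of each
#' stage uses t = 2 without shortcut, the remaining blocks t = 6 with
#' shortcut.
#'
#' @return A data frame with columns `stage`, `operator`, `t_first`,
#'   `t_rest`, `out_channels`, `repeats`.
#' @export
default_stage_plan <- function() {
  data.frame(
    stage = 1:15,
    operator = c("root", "shield", "sfsam", "maxblurpool",
                 "shield", "sfsam", "maxblurpool",
                 "shield", "sfsam", "maxblurpool",
                 "shield", "sfsam", "maxblurpool",
                 "globalavgpool", "head"),
    t_first = c(NA, 2, NA, NA, 2, NA, NA, 2, NA, NA, 2, NA, NA, NA, NA),
    t_rest = c(NA, 6, NA, NA, 6, NA, NA, 6, NA, NA, 6, NA, NA, NA, NA),
    out_channels = c(32, 64, 64, 64, 128, 128, 128, 192, 192, 192,
                     256, 256, 256, 256, NA),
    repeats = c(1, 2, 1, 1, 4, 1, 1, 5, 1, 1, 4, 1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
}

#' Scale a stage plan by a width multiplier
#'
#' Every stage channel count is scaled by `m` and rounded to the nearest
#' multiple of `groups` so that all attention sites stay divisible by the
#' group count.  `m = 0.75` turns the default channels (32, 64, 128, 192,
#' 256) into (24, 48, 96, 144, 192).
#'
#' @param plan A stage plan from [default_stage_plan()].
#' @param m Width multiplier in (0, 1].
#' @param groups Attention group count used for rounding (default 4).
#' @return The scaled plan.
#' @export
apply_width_multiplier <- function(plan, m, groups = 4L) {
  if (m <= 0 || m > 1) stop("apply_width_multiplier: m must be in (0, 1]")
  if (m == 1) return(plan)
  sc <- function(c) {
    if (is.na(c)) return(c)
    c2 <- round(c * m / groups) * groups
    if (c2 < groups)
      stop("apply_width_multiplier: channel count ", c,
           " collapses below one group at m = ", m)
    c2
  }
  plan$out_channels <- vapply(plan$out_channels, sc, numeric(1))
  plan
}

#' Network configuration
#'
#' @param width_multiplier Uniform channel scale factor (1.0 or 0.75 in the
#'   published variants).
#' @param groups Attention group count `g` (default 4).
#' @param use_sfsam Include the four attention sites (default `TRUE`);
#'   `FALSE` elides them and changes nothing else.
#' @param num_classes Output classes (default 2).
#' @param dropout_rate Channel dropout rate of the head (default 0.2).
#' @param input_size Input image side in pixels (default 224; must be even).
#' @param attention_kernel,attention_gate Passed to [attention_config()].
#' @param stem_filters,branch_filters Root-module widths before width
#'   scaling (defaults 16 and 56).
#' @param split_r Shield-block split ratio `r` (default 6).
#' @param stage_plan Stage plan before width scaling.
#' @return An object of class `seedsort_config`.
#' @export
seedsort_config <- function(width_multiplier = 1.0, groups = 4L,
                            use_sfsam = TRUE, num_classes = 2L,
                            dropout_rate = 0.2, input_size = 224L,
                            attention_kernel = 7L,
                            attention_gate = "softmax",
                            stem_filters = 16L, branch_filters = 56L,
                            split_r = 6L,
                            stage_plan = default_stage_plan()) {
  if (input_size %% 2L != 0L) stop("seedsort_config: input_size must be even")
  structure(list(
    width_multiplier = width_multiplier,
    groups = as.integer(groups),
    use_sfsam = use_sfsam,
    num_classes = as.integer(num_classes),
    dropout_rate = dropout_rate,
    input_size = as.integer(input_size),
    attention = attention_config(groups = groups, kernel = attention_kernel,
                                 gate = attention_gate),
    stem_filters = as.integer(stem_filters),
    branch_filters = as.integer(branch_filters),
    split_r = as.integer(split_r),
    stage_plan = stage_plan
  ), class = "seedsort_config")
}

scale_width <- function(c, m, groups) {
  if (m == 1) return(as.integer(c))
  c2 <- as.integer(round(c * m / groups) * groups)
  if (c2 < groups) stop("width multiplier collapses ", c, " channels")
  c2
}

#' Build a SeedSortNet network
#'
#' @param config A [seedsort_config()].
#' @param rng_seed Optional integer seed for the weight initialization
#'   (uses a private RNG stream).
#' @return An object of class `seedsortnet`: a callable network mapping
#'   `input_size x input_size x 3` image batches to `num_classes` raw
#'   scores via [network_forward()] or [predict.seedsortnet()].
#' @export
build_network <- function(config = seedsort_config(), rng_seed = NULL) {
  if (!is.null(rng_seed))
    return(with_seed(rng_seed, build_network(config, rng_seed = NULL)))
  m <- config$width_multiplier
  g <- config$groups
  plan <- apply_width_multiplier(config$stage_plan, m, g)
  stem_f <- scale_width(config$stem_filters, m, g)
  branch_f <- scale_width(config$branch_filters, m, g)

  layers <- list()
  cur_c <- 3L
  n_shield <- 0L; n_sfsam <- 0L; n_pool <- 0L
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    nm <- sprintf("stage%02d_%s", row$stage, row$operator)
    if (row$operator == "root") {
      layers[[nm]] <- new_root(cur_c, stem_f, branch_f, name = nm)
      cur_c <- 2L * stem_f
    } else if (row$operator == "shield") {
      for (rblock in seq_len(row$repeats)) {
        first <- rblock == 1L
        out_c <- as.integer(row$out_channels)
        sp <- shield_block_spec(
          in_channels = cur_c, out_channels = out_c,
          reduction_t = if (first) row$t_first else row$t_rest,
          split_r = config$split_r,
          use_shortcut = !first
        )
        bnm <- sprintf("%s_block%d", nm, rblock)
        layers[[bnm]] <- new_shield(sp, name = bnm)
        cur_c <- out_c
        n_shield <- n_shield + 1L
      }
    } else if (row$operator == "sfsam") {
      if (config$use_sfsam) {
        layers[[nm]] <- new_sfsam(cur_c, config$attention, name = nm)
        n_sfsam <- n_sfsam + 1L
      }
    } else if (row$operator == "maxblurpool") {
      layers[[nm]] <- new_mbp(name = nm)
      n_pool <- n_pool + 1L
    } else if (row$operator == "globalavgpool") {
      layers[[nm]] <- new_gap(name = nm)
    } else if (row$operator == "head") {
      layers[[paste0(nm, "_dropout")]] <- new_dropout(config$dropout_rate,
                                                      name = paste0(nm, "_dropout"))
      layers[[paste0(nm, "_fc")]] <- new_fc(cur_c, config$num_classes,
                                            name = paste0(nm, "_fc"))
    } else stop("unknown operator in stage plan: ", row$operator)
  }

  net <- new.env(parent = emptyenv())
  net$layers <- layers
  net$config <- config
  net$plan <- plan
  net$norm <- NULL
  net$counts <- c(shield = n_shield, sfsam = n_sfsam, pool = n_pool)
  class(net) <- "seedsortnet"
  net
}

#' Raw forward pass
#'
#' @param network A [build_network()] result.
#' @param x An `H x W x 3` image or `H x W x 3 x N` batch with
#'   `H = W = input_size`; values must be finite.  No input normalization
#'   is applied here (see [predict.seedsortnet()]).
#' @param training Run in training mode (batch statistics, dropout).
#' @return An `N x num_classes` matrix of raw class scores.
#' @export
network_forward <- function(network, x, training = FALSE) {
  x <- as_batch(x)
  d <- dim(x)
  cfg <- network$config
  if (d[1] != cfg$input_size || d[2] != cfg$input_size || d[3] != 3L)
    stop(sprintf("network_forward: expected %d x %d x 3 input, got %d x %d x %d",
                 cfg$input_size, cfg$input_size, d[1], d[2], d[3]))
  if (!all(is.finite(x))) stop("network_forward: non-finite input values")
  for (ly in network$layers) x <- ly_forward(ly, x, training)
  x
}

network_backward <- function(network, dscores) {
  g <- dscores
  for (ly in rev(network$layers)) g <- ly_backward(ly, g)
  invisible(g)
}

#' Predict classes or probabilities
#'
#' Applies the per-channel input standardization recorded at training time
#' (if any), runs an inference-mode forward pass and returns scores,
#' softmax probabilities or hard class labels (1 = positive/normal,
#' 0 = negative/abnormal).
#'
#' @param object A `seedsortnet` network.
#' @param x Image or batch as in [network_forward()].
#' @param type `"score"`, `"prob"` or `"class"`.
#' @param ... Unused.
#' @export
predict.seedsortnet <- function(object, x,
                                type = c("score", "prob", "class"), ...) {
  type <- match.arg(type)
  x <- as_batch(x)
  if (!is.null(object$norm)) {
    d <- dim(x)
    x <- (x - bcast_channel(object$norm$mean, d)) /
      bcast_channel(object$norm$sd, d)
  }
  s <- network_forward(object, x, training = FALSE)
  if (type == "score") return(s)
  p <- exp(s - apply(s, 1, max))
  p <- p / rowSums(p)
  if (type == "prob") return(p)
  as.integer(max.col(p) == 2L)  # column 2 is the positive class
}

#' Analytic shape trace through the stage plan
#'
#' @param network A `seedsortnet` network.
#' @param input_size Input side length (default: the configured one).
#' @return A data frame with one row per stage: `stage`, `operator`, the
#'   stage's input `H`, `W`, `C`, and its output `H_out`, `W_out`, `C_out`.
#' @export
shape_trace <- function(network, input_size = network$config$input_size) {
  plan <- network$plan
  h <- input_size; c <- 3L
  rows <- list()
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    hin <- h; cin <- c
    if (row$operator == "root") { h <- h %/% 2L; c <- as.integer(row$out_channels) }
    else if (row$operator == "shield") c <- as.integer(row$out_channels)
    else if (row$operator == "maxblurpool") h <- as.integer(ceiling(h / 2))
    else if (row$operator == "globalavgpool") h <- 1L
    else if (row$operator == "head") { h <- NA_integer_; c <- network$config$num_classes }
    rows[[i]] <- data.frame(stage = row$stage, operator = row$operator,
                            H = hin, W = hin, C = cin,
                            H_out = h, W_out = h, C_out = c)
  }
  do.call(rbind, rows)
}

#' @export
print.seedsortnet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "SeedSortNet (width %.2fx, g = %d%s, input %d, %d classes)\n",
    cfg$width_multiplier, cfg$groups,
    if (cfg$use_sfsam) "" else ", no SFSAM", cfg$input_size, cfg$num_classes))
  cat(sprintf("  %d Shield-blocks, %d SFSAM sites, %d pooling stages\n",
              x$counts["shield"], x$counts["sfsam"], x$counts["pool"]))
  cat(sprintf("  %s learnable parameters\n",
              format(count_params(x)$total_params, big.mark = ",")))
  invisible(x)
}

# ---- checkpointing ----------------------------------------------------------

collect_state <- function(network) {
  state <- list()
  for (top in network$layers)
    walk_layers(top, function(l) {
      entry <- list(params = l$params)
      if (!is.null(l$rmean)) entry$rmean <- l$rmean
      if (!is.null(l$rvar)) entry$rvar <- l$rvar
      state[[l$name]] <<- entry
    })
  state
}

#' Save / load a trained network
#'
#' The checkpoint stores the configuration, all parameter arrays, batch-norm
#' running statistics and the input-normalization record.
#'
#' @param network A `seedsortnet` network.
#' @param path File path for the checkpoint.
#' @export
save_network <- function(network, path) {
  saveRDS(list(config = network$config, state = collect_state(network),
               norm = network$norm), path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  ck <- readRDS(path)
  net <- build_network(ck$config, rng_seed = 1L)
  for (top in net$layers)
    walk_layers(top, function(l) {
      entry <- ck$state[[l$name]]
      if (is.null(entry)) stop("checkpoint is missing layer ", l$name)
      l$params <- entry$params
      if (!is.null(entry$rmean)) l$rmean <- entry$rmean
      if (!is.null(entry$rvar)) l$rvar <- entry$rvar
    })
  net$norm <- ck$norm
  net
}
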