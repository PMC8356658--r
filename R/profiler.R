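# Deterministic parameter and multiply-accumulate accounting.
#
# Counting conventions (recorded in every report):
#   * parameters: every learnable array as built -- convolution weights and
#     biases, batch-norm affine pairs (gamma, beta), attention filters and
#     biases, head weights and bias.  Batch-norm running statistics, the
#     fixed blur kernel and pooling contribute nothing.
#   * MACs: one multiply-accumulate counted as one FLOP; convolutions cost
#     Hout*Wout*k^2*Cin*Cout (divided by Cin for depthwise, i.e.
#     Hout*Wout*k^2*C), the attention convolutions Hout*Wout*k^2*2 per
#     group, the fully-connected head in*out.  Normalization, activations,
#     pooling, softmax and the element-wise attention arithmetic are
#     excluded by default; `include_bias_macs` adds one op per output
#     element of biased layers for the alternative reading.

profile_rows <- function(ly, h, w, include_bias) {
  op_row <- function(l, ho, wo, co, macs) {
    data.frame(layer = l$name, operator = l$type,
               out_shape = sprintf("%dx%dx%d", ho, wo, co),
               params = layer_own_params(l), macs = macs,
               stringsAsFactors = FALSE)
  }
  layer_own_params <- function(l) sum(vapply(l$params, length, 0))

  switch(ly$type,
    cba = {
      ho <- as.integer(ceiling(h / ly$stride)); wo <- as.integer(ceiling(w / ly$stride))
      k2 <- ly$kernel^2
      macs <- if (ly$depthwise) ho * wo * k2 * ly$cout
              else ho * wo * k2 * ly$cin * ly$cout
      if (include_bias && ly$use_bias) macs <- macs + ho * wo * ly$cout
      list(rows = op_row(ly, ho, wo, ly$cout, macs), h = ho, w = wo, c = ly$cout)
    },
    mbp = {
      ho <- as.integer(ceiling(h / 2)); wo <- as.integer(ceiling(w / 2))
      list(rows = op_row(ly, ho, wo, NA_integer_, 0), h = ho, w = wo, c = NA)
    },
    root = {
      ch <- ly$children
      stem <- profile_rows(ch$stem, h, w, include_bias)
      pool <- profile_rows(ch$pool, stem$h, stem$w, include_bias)
      b2a <- profile_rows(ch$b2a, stem$h, stem$w, include_bias)
      b2b <- profile_rows(ch$b2b, b2a$h, b2a$w, include_bias)
      rows <- rbind(stem$rows, pool$rows, b2a$rows, b2b$rows)
      list(rows = rows, h = pool$h, w = pool$w, c = ly$cout)
    },
    shield = {
      ch <- ly$children
      rows <- NULL
      for (nm in c("m1", "m2", "m3", "m4", "s1", "s2")) {
        pr <- profile_rows(ch[[nm]], h, w, include_bias)
        rows <- rbind(rows, pr$rows)
      }
      list(rows = rows, h = h, w = w, c = ly$spec$out_channels)
    },
    sfsam = {
      g <- ly$config$groups
      k2 <- ly$config$kernel^2
      macs <- g * h * w * 2 * k2
      if (include_bias) macs <- macs + g * h * w
      list(rows = op_row(ly, h, w, ly$C, macs), h = h, w = w, c = ly$C)
    },
    gap = list(rows = op_row(ly, 1L, 1L, NA_integer_, 0), h = 1L, w = 1L, c = NA),
    dropout = list(rows = NULL, h = h, w = w, c = NA),
    fc = {
      macs <- ly$cin * ly$cout
      if (include_bias) macs <- macs + ly$cout
      list(rows = op_row(ly, 1L, 1L, ly$cout, macs), h = 1L, w = 1L, c = ly$cout)
    },
    stop("profile: unknown layer type ", ly$type)
  )
}

#' Profile a network's parameter and MAC budget
#'
#' Walks the built network layer by layer, counting learnable parameters
#' from the actual parameter arrays and multiply-accumulates from the layer
#' geometry at the given input size.
#'
#' @param network A `seedsortnet` network (or any single layer).
#' @param input_size Input side length in pixels (default: configured size).
#' @param include_bias_macs Count one additional op per output element of
#'   biased layers (alternative convention; default `FALSE`).
#' @return An object of class `ssn_profile`: a list with `total_params`,
#'   `total_macs`, `per_layer` (data frame) and `conventions`.
#' @export
profile_network <- function(network, input_size = NULL,
                            include_bias_macs = FALSE) {
  if (inherits(network, "seedsortnet")) {
    if (is.null(input_size)) input_size <- network$config$input_size
    h <- input_size; w <- input_size
    rows <- NULL
    for (ly in network$layers) {
      pr <- profile_rows(ly, h, w, include_bias_macs)
      rows <- rbind(rows, pr$rows)
      h <- pr$h; w <- pr$w
    }
  } else if (inherits(network, "ssn_layer")) {
    if (is.null(input_size)) stop("profile_network: input_size required for a bare layer")
    pr <- profile_rows(network, input_size, input_size, include_bias_macs)
    rows <- pr$rows
  } else stop("profile_network: not a network or layer")
  structure(list(
    total_params = sum(rows$params),
    total_macs = sum(rows$macs),
    per_layer = rows,
    conventions = list(
      flops_are_macs = TRUE,
      count_bias_macs = include_bias_macs,
      count_norm_act_pool_elementwise = FALSE,
      params_include_bn_affine = TRUE,
      params_include_conv_bias = TRUE
    )
  ), class = "ssn_profile")
}

#' Count learnable parameters
#'
#' @param network A `seedsortnet` network.
#' @return An `ssn_profile` whose `total_params` and per-layer `params`
#'   fields are the counts of interest.
#' @export
count_params <- function(network) {
  profile_network(network,
                  input_size = if (inherits(network, "seedsortnet"))
                    network$config$input_size else 1L)
}

#' Count multiply-accumulates at a given input size
#'
#' @param network A `seedsortnet` network.
#' @param input_size Input side length in pixels.
#' @param include_bias_macs See [profile_network()].
#' @return An `ssn_profile` whose `total_macs` field is the count of
#'   interest.
#' @export
count_macs <- function(network, input_size = network$config$input_size,
                       include_bias_macs = FALSE) {
  profile_network(network, input_size, include_bias_macs)
}

#' @export
print.ssn_profile <- function(x, ...) {
  cat(sprintf("Total learnable parameters: %s (%.6f M)\n",
              format(x$total_params, big.mark = ","), x$total_params / 1e6))
  cat(sprintf("Total multiply-accumulates: %s (%.2f M)\n",
              format(x$total_macs, big.mark = ","), x$total_macs / 1e6))
  cat(sprintf("Layers counted: %d; bias MACs %s\n", nrow(x$per_layer),
              if (x$conventions$count_bias_macs) "included" else "excluded"))
  invisible(x)
}

#' Reference budgets of the published architecture variants
#'
#' Model-size and computation budgets reported for the original release of
#' the architecture family, used by [budget_reconciliation()] as the
#' comparison column.
#'
#' @return A data frame with columns `variant`, `params_M`, `flops_M`.
#' @export
reference_budgets <- function() {
  data.frame(
    variant = c("default", "no_sfsam", "g1", "g8", "g16", "width075"),
    params_M = c(0.400, 0.399, 0.399, 0.402, 0.405, 0.23),
    flops_M = c(512.06, 505.26, 506.56, 518.85, 532.45, 338.64),
    stringsAsFactors = FALSE
  )
}

variant_config <- function(variant) {
  switch(variant,
    default = seedsort_config(),
    no_sfsam = seedsort_config(use_sfsam = FALSE),
    g1 = seedsort_config(groups = 1L),
    g8 = seedsort_config(groups = 8L),
    g16 = seedsort_config(groups = 16L),
    width075 = seedsort_config(width_multiplier = 0.75),
    stop("unknown variant: ", variant)
  )
}

#' Reconcile computed budgets against the published ones
#'
#' Builds every published variant (default, no-SFSAM, g in {1, 8, 16},
#' 0.75x width), profiles it at the given input size, and tabulates the
#' computed parameter and MAC totals alongside the reference budgets with
#' absolute differences.
#'
#' @param input_size Input side length (default 224).
#' @param rng_seed Seed for weight initialization (counts do not depend on
#'   the weights' values, only on their shapes).
#' @param include_bias_macs See [profile_network()].
#' @return A data frame with one row per variant.
#' @export
budget_reconciliation <- function(input_size = 224L, rng_seed = 1L,
                                  include_bias_macs = FALSE) {
  ref <- reference_budgets()
  rows <- lapply(ref$variant, function(v) {
    net <- build_network(variant_config(v), rng_seed = rng_seed)
    pr <- profile_network(net, input_size, include_bias_macs)
    data.frame(variant = v,
               params = pr$total_params,
               params_M = pr$total_params / 1e6,
               macs_M = pr$total_macs / 1e6,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ref_params_M <- ref$params_M
  out$ref_flops_M <- ref$flops_M
  out$d_params_M <- abs(out$params_M - out$ref_params_M)
  out$d_flops_M <- abs(out$macs_M - out$ref_flops_M)
  out
}

#' Export an architecture summary as JSON
#'
#' @param network A `seedsortnet` network.
#' @param path Optional file path; when omitted the JSON string is returned.
#' @param input_size Input side length for the shape/MAC columns.
#' @return The JSON string, invisibly when written to `path`.
#' @export
export_architecture <- function(network, path = NULL,
                                input_size = network$config$input_size) {
  pr <- profile_network(network, input_size)
  obj <- list(
    config = network$config[c("width_multiplier", "groups", "use_sfsam",
                              "num_classes", "dropout_rate", "input_size")],
    totals = list(params = pr$total_params, macs = pr$total_macs),
    layers = pr$per_layer
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
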