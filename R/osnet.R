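# OSNet: orthogonal-projection channel attention + residual + channel
# shuffle, stacked into a multi-scale backbone emitting S3/S4/S5 (strides
# 8/16/32).
#
# The attention path projects each channel of a square (b, c, n, n) feature
# map onto that channel's frozen n x n orthogonal filter (elementwise
# product, spatial sum), squeezes the result through a two-layer MLP with
# ReLU + sigmoid, and reweights the channels. Filters are frozen: they are
# an initialization-time regularizer, never updated by the optimizer.

#' Project each channel onto its orthogonal filter
#'
#' `f[b, i] = sum_{h,w} F[b, i, , ] * W_i` — the channel-wise projection
#' coefficient of the feature map onto the bank's orthogonal subspace.
#' Differentiable in `F` (the bank is constant).
#'
#' @param x feature map, array or `ag_node` of shape `(b, c, h, w)` with
#'   `h == w == bank$n` and `c == bank$c`.
#' @param bank a `filter_bank`.
#' @return `ag_node` of shape `(b, c)` (use [ag_value()] for the numbers).
#' @export
orthogonal_projection <- function(x, bank) {
  x <- as_ag(x)
  d <- dim(x$value)
  if (d[3L] != d[4L])
    stop("attention path requires a square feature map (h == w); got ",
         d[3L], " x ", d[4L], ". Enable pad_to_square in the backbone ",
         "config to zero-pad non-square maps.")
  if (d[3L] != bank$n)
    stop("feature side ", d[3L], " does not match filter side ", bank$n)
  if (d[2L] != bank$c)
    stop("channel count ", d[2L], " does not match bank size ", bank$c)
  bsz <- d[1L]; cc <- d[2L]; n <- d[3L]
  # (b, c, n, n) * per-channel filter, then sum over space
  Wrep <- aperm(array(rep(bank$matrices, bsz), c(cc, n, n, bsz)),
                c(4L, 1L, 2L, 3L))
  prod_ <- x$value * Wrep
  dim(prod_) <- c(bsz * cc, n * n)
  f <- matrix(rowSums(prod_), bsz, cc)
  ag_node(f, list(x),
          function(g) {
            gfull <- array(g, d)   # (b, c) recycled over space
            list(gfull * Wrep)
          },
          x$requires_grad)
}

#' Parameters of the channel-attention MLP
#' @param c channel count.
#' @param reduction hidden-width divisor; hidden dim is
#'   `max(1, c / reduction)` (squeeze-and-excitation convention).
#' @return list with `fc1`, `fc2` linear parameters.
#' @export
attention_mlp_params <- function(c, reduction = 16) {
  hidden <- max(1L, as.integer(c %/% reduction))
  list(fc1 = linear_param(c, hidden), fc2 = linear_param(hidden, c))
}

#' Channel-attention weights from projection coefficients
#'
#' `alpha = sigmoid(FC2(relu(FC1(f))))`; every entry lies strictly in (0, 1).
#'
#' @param f `(b, c)` matrix or node of projection coefficients.
#' @param mlp parameters from [attention_mlp_params()].
#' @return `ag_node` of shape `(b, c)`.
#' @export
attention_weights <- function(f, mlp) {
  h <- ag_relu(ag_linear(f, mlp$fc1$W, mlp$fc1$b))
  ag_sigmoid(ag_linear(h, mlp$fc2$W, mlp$fc2$b))
}

#' Channel-shuffle permutation
#' @param c channel count.
#' @param groups group count; must divide `c`.
#' @return integer permutation of `1:c` (reshape to `(groups, c/groups)`,
#'   transpose, flatten).
#' @export
channel_shuffle_perm <- function(c, groups) {
  if (c %% groups != 0)
    stop("channel count ", c, " not divisible by groups ", groups)
  as.vector(matrix(seq_len(c), nrow = groups, byrow = TRUE))
}

#' Shuffle the channels of a feature map
#'
#' Deterministic interleaving permutation used after the residual merge to
#' mix information across channel groups; spatial values are untouched.
#'
#' @param x array or node `(b, c, h, w)`.
#' @param groups group count dividing `c`.
#' @return same type as `x` with channels permuted.
#' @export
channel_shuffle <- function(x, groups) {
  cc <- if (inherits(x, "ag_node")) dim(x$value)[2L] else dim(x)[2L]
  perm <- channel_shuffle_perm(cc, groups)
  if (inherits(x, "ag_node")) ag_permute_channels(x, perm)
  else x[, perm, , , drop = FALSE]
}

#' OSNet block configuration
#' @param in_channels,out_channels positive integers.
#' @param stride 1 or 2.
#' @param shuffle_groups groups for the channel shuffle (must divide
#'   `out_channels`).
#' @param attention_reduction hidden-width divisor of the attention MLP.
#' @param use_norm apply batch normalization after each convolution.
#' @param seed integer seed for parameter initialization.
#' @return an `osnet_block_config` list.
#' @export
osnet_block_config <- function(in_channels, out_channels, stride = 1L,
                               shuffle_groups = 2L, attention_reduction = 16L,
                               use_norm = TRUE, seed = 0L) {
  if (!stride %in% c(1L, 2L)) stop("stride must be 1 or 2")
  if (out_channels %% shuffle_groups != 0)
    stop("out_channels must be divisible by shuffle_groups")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 stride = as.integer(stride),
                 shuffle_groups = as.integer(shuffle_groups),
                 attention_reduction = as.integer(attention_reduction),
                 use_norm = isTRUE(use_norm),
                 seed = as.integer(seed)),
            class = "osnet_block_config")
}

#' Initialize the trainable parameters of one OSNet block
#' @param cfg an [osnet_block_config()].
#' @return nested list of `ag_param` leaves (+ batch-norm states).
#' @export
osnet_block_params <- function(cfg) {
  with_seed(cfg$seed, {
    p <- list(
      conv1 = conv_param(cfg$out_channels, cfg$in_channels, 3L),
      conv2 = conv_param(cfg$out_channels, cfg$out_channels, 3L),
      attn = attention_mlp_params(cfg$out_channels, cfg$attention_reduction)
    )
    if (cfg$use_norm) {
      p$bn1 <- bn_param(cfg$out_channels)
      p$bn2 <- bn_param(cfg$out_channels)
    }
    if (cfg$in_channels != cfg$out_channels || cfg$stride != 1L) {
      p$short <- conv_param(cfg$out_channels, cfg$in_channels, 1L)
      if (cfg$use_norm) p$bn_s <- bn_param(cfg$out_channels)
    }
    p
  })
}

#' Forward pass of one OSNet block
#'
#' Main branch: 3x3 conv (stride) -> norm -> ReLU -> 3x3 conv -> norm,
#' giving `F`; attention reweights `F` channel-wise using the orthogonal
#' projection onto `bank`; shortcut branch is the identity (or a strided 1x1
#' conv when shapes change); the merged map is channel-shuffled and passed
#' through a single final ReLU (a ReLU before the shuffle would be
#' redundant, since the shuffle is a sign-preserving permutation).
#'
#' @param x input node/array `(b, in_channels, h, w)`.
#' @param cfg an [osnet_block_config()].
#' @param bank `filter_bank` with `c = out_channels` and `n` equal to the
#'   output spatial side.
#' @param params from [osnet_block_params()].
#' @param training batch-norm mode.
#' @param alpha_override optional fixed `(b, c)` attention matrix (used by
#'   composition oracles); `NULL` computes attention normally.
#' @return `ag_node` of shape `(b, out_channels, h', w')`.
#' @export
osnet_block_forward <- function(x, cfg, bank, params, training = TRUE,
                                alpha_override = NULL) {
  x <- as_ag(x)
  h <- ag_conv2d(x, params$conv1$W, params$conv1$b, stride = cfg$stride,
                 pad = 1L)
  if (cfg$use_norm)
    h <- ag_batchnorm(h, params$bn1$gamma, params$bn1$beta,
                      params$bn1$state, training)
  h <- ag_relu(h)
  F_ <- ag_conv2d(h, params$conv2$W, params$conv2$b, stride = 1L, pad = 1L)
  if (cfg$use_norm)
    F_ <- ag_batchnorm(F_, params$bn2$gamma, params$bn2$beta,
                       params$bn2$state, training)
  alpha <- if (is.null(alpha_override)) {
    f <- orthogonal_projection(F_, bank)
    attention_weights(f, params$attn)
  } else as_ag(alpha_override)
  F_attn <- ag_channel_scale(F_, alpha)
  F_res <- if (is.null(params$short)) x else {
    s <- ag_conv2d(x, params$short$W, params$short$b, stride = cfg$stride,
                   pad = 0L)
    if (cfg$use_norm)
      s <- ag_batchnorm(s, params$bn_s$gamma, params$bn_s$beta,
                        params$bn_s$state, training)
    s
  }
  merged <- ag_add(F_attn, F_res)
  ag_relu(channel_shuffle(merged, cfg$shuffle_groups))
}

#' Backbone configuration
#'
#' The stem is two stride-2 3x3 convolutions (total stride 4); each stage
#' halves the spatial side with its first block, so the three stage outputs
#' sit at strides 8, 16 and 32 (S3, S4, S5). Filter banks are built lazily
#' per encountered (channels, spatial side) pair from the run seed and
#' cached.
#'
#' @param input_channels image channels (1 for grayscale).
#' @param stem_channels stem width.
#' @param stage_channels,stage_depths integer vectors of length 3.
#' @param shuffle_groups,attention_reduction per-block settings.
#' @param ortho_mode filter-bank flavour, `"special_orthogonal"` or
#'   `"gram_schmidt"`.
#' @param use_norm batch normalization toggle.
#' @param pad_to_square zero-pad non-square maps before attention.
#' @param seed integer seed.
#' @return a `backbone_config` list.
#' @export
backbone_config <- function(input_channels = 1L, stem_channels = 32L,
                            stage_channels = c(64L, 128L, 256L),
                            stage_depths = c(2L, 2L, 2L),
                            shuffle_groups = 2L, attention_reduction = 16L,
                            ortho_mode = "special_orthogonal",
                            use_norm = TRUE, pad_to_square = FALSE,
                            seed = 0L) {
  stopifnot(length(stage_channels) == 3L, length(stage_depths) == 3L)
  structure(list(input_channels = as.integer(input_channels),
                 stem_channels = as.integer(stem_channels),
                 stage_channels = as.integer(stage_channels),
                 stage_depths = as.integer(stage_depths),
                 shuffle_groups = as.integer(shuffle_groups),
                 attention_reduction = as.integer(attention_reduction),
                 ortho_mode = ortho_mode, use_norm = isTRUE(use_norm),
                 pad_to_square = isTRUE(pad_to_square),
                 seed = as.integer(seed)),
            class = "backbone_config")
}

# lazily build / fetch the frozen bank for a (channels, side) pair
bank_for <- function(cache, c, side, mode, seed) {
  key <- paste0(mode, "_", c, "_", side)
  b <- cache[[key]]
  if (is.null(b)) {
    b <- build_filter_bank(c, side, mode, seed = seed + c * 131L + side * 17L)
    cache[[key]] <- b
  }
  b
}

#' Assemble an OSNet backbone
#'
#' @param cfg a [backbone_config()].
#' @return a `backbone` module: list with `cfg`, `params`, `banks` (lazy
#'   cache) and `forward(x, training)` returning `list(S3, S4, S5)`.
#' @export
build_backbone <- function(cfg = backbone_config()) {
  params <- with_seed(cfg$seed, {
    p <- list(
      stem1 = conv_param(cfg$stem_channels, cfg$input_channels, 3L),
      stem2 = conv_param(cfg$stem_channels, cfg$stem_channels, 3L)
    )
    if (cfg$use_norm) {
      p$bn_stem1 <- bn_param(cfg$stem_channels)
      p$bn_stem2 <- bn_param(cfg$stem_channels)
    }
    p
  })
  stages <- list()
  in_ch <- cfg$stem_channels
  for (s in 1:3) {
    blocks <- list()
    for (d in seq_len(cfg$stage_depths[s])) {
      bcfg <- osnet_block_config(
        in_channels = in_ch, out_channels = cfg$stage_channels[s],
        stride = if (d == 1L) 2L else 1L,
        shuffle_groups = cfg$shuffle_groups,
        attention_reduction = cfg$attention_reduction,
        use_norm = cfg$use_norm,
        seed = cfg$seed + 1000L * s + d)
      blocks[[d]] <- list(cfg = bcfg, params = osnet_block_params(bcfg))
      in_ch <- cfg$stage_channels[s]
    }
    stages[[s]] <- blocks
  }
  banks <- new.env(parent = emptyenv())
  mod <- list(cfg = cfg, params = params, stages = stages, banks = banks)
  mod$forward <- function(x, training = TRUE) backbone_forward(mod, x, training)
  class(mod) <- "backbone"
  mod
}

maybe_pad_square <- function(x, enable) {
  d <- dim(ag_value(x))
  if (d[3L] == d[4L]) return(x)
  if (!enable)
    stop("non-square feature map (", d[3L], " x ", d[4L], "); set ",
         "pad_to_square = TRUE to zero-pad symmetrically")
  side <- max(d[3L], d[4L])
  # symmetric zero-padding to square via conv-free embedding
  x <- as_ag(x)
  v <- array(0, c(d[1L], d[2L], side, side))
  oy <- (side - d[3L]) %/% 2L; ox <- (side - d[4L]) %/% 2L
  v[, , oy + seq_len(d[3L]), ox + seq_len(d[4L])] <- x$value
  ag_node(v, list(x),
          function(g) list(g[, , oy + seq_len(d[3L]), ox + seq_len(d[4L]),
                             drop = FALSE]),
          x$requires_grad)
}

#' Run the backbone
#' @param mod a `backbone` from [build_backbone()].
#' @param x node/array `(b, input_channels, side, side)`, side divisible
#'   by 32.
#' @param training batch-norm mode.
#' @return list of `ag_node`s `S3`, `S4`, `S5` at strides 8/16/32.
#' @export
backbone_forward <- function(mod, x, training = TRUE) {
  cfg <- mod$cfg
  d <- dim(ag_value(x))
  if (d[3L] %% 32L != 0L || d[4L] %% 32L != 0L)
    stop("input side must be divisible by 32; got ", d[3L], " x ", d[4L])
  p <- mod$params
  h <- ag_conv2d(as_ag(x), p$stem1$W, p$stem1$b, stride = 2L, pad = 1L)
  if (cfg$use_norm)
    h <- ag_batchnorm(h, p$bn_stem1$gamma, p$bn_stem1$beta,
                      p$bn_stem1$state, training)
  h <- ag_relu(h)
  h <- ag_conv2d(h, p$stem2$W, p$stem2$b, stride = 2L, pad = 1L)
  if (cfg$use_norm)
    h <- ag_batchnorm(h, p$bn_stem2$gamma, p$bn_stem2$beta,
                      p$bn_stem2$state, training)
  h <- ag_relu(h)
  outs <- vector("list", 3L)
  for (s in 1:3) {
    for (blk in mod$stages[[s]]) {
      h <- maybe_pad_square(h, cfg$pad_to_square)
      side_out <- dim(ag_value(h))[3L] %/% blk$cfg$stride
      bank <- bank_for(mod$banks, blk$cfg$out_channels, side_out,
                       cfg$ortho_mode, cfg$seed)
      h <- osnet_block_forward(h, blk$cfg, bank, blk$params, training)
    }
    outs[[s]] <- h
  }
  names(outs) <- c("S3", "S4", "S5")
  outs
}
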