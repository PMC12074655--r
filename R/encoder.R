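# Hybrid encoder: AIFI (deformable attention applied to the deepest plane
# S5 only, with residual + layer-norm and an FFN) followed by CCFM
# (PAN-style top-down + bottom-up cross-scale fusion built from RepBlocks).
# Only S5 is expensive to attend over; S3/S4 join through convolutional
# fusion, which is what keeps the encoder fast.

#' RepBlock parameters
#'
#' Train-time branches: a 3x3 conv, a 1x1 conv and (when `in == out`) an
#' identity path, summed before the activation. [reparameterize()] merges
#' the branches into a single 3x3 conv for deployment.
#'
#' @param cin,cout channel counts; the identity branch exists only when
#'   they are equal.
#' @param seed integer seed.
#' @return list with `conv3`, `conv1`, `identity` flag.
#' @export
repblock_params <- function(cin, cout, seed = 0L) {
  with_seed(seed, list(
    conv3 = conv_param(cout, cin, 3L),
    conv1 = conv_param(cout, cin, 1L),
    identity = cin == cout
  ))
}

#' RepBlock forward pass
#' @param x node/array `(b, cin, h, w)`.
#' @param params from [repblock_params()] (train mode) or
#'   [reparameterize()] (deploy mode).
#' @param mode `"train"` (multi-branch) or `"deploy"` (merged single conv).
#' @return `ag_node` `(b, cout, h, w)`.
#' @export
repblock_forward <- function(x, params, mode = c("train", "deploy")) {
  mode <- match.arg(mode)
  x <- as_ag(x)
  if (mode == "deploy") {
    if (is.null(params$W_merged))
      stop("deploy mode needs merged parameters from reparameterize()")
    return(ag_relu(ag_conv2d(x, params$W_merged, params$b_merged,
                             stride = 1L, pad = 1L)))
  }
  y <- ag_add(ag_conv2d(x, params$conv3$W, params$conv3$b, stride = 1L,
                        pad = 1L),
              ag_conv2d(x, params$conv1$W, params$conv1$b, stride = 1L,
                        pad = 0L))
  if (isTRUE(params$identity)) y <- ag_add(y, x)
  ag_relu(y)
}

#' Merge RepBlock branches into one 3x3 convolution
#'
#' The 1x1 kernel embeds in the center tap of a 3x3 kernel and the identity
#' branch is a centered unit kernel, so the three branches sum algebraically
#' into a single conv with identical output.
#'
#' @param params from [repblock_params()].
#' @return the same list plus `W_merged`, `b_merged`.
#' @export
reparameterize <- function(params) {
  W3 <- ag_value(params$conv3$W)
  W1 <- ag_value(params$conv1$W)
  Wm <- W3
  Wm[, , 2L, 2L] <- Wm[, , 2L, 2L] + W1[, , 1L, 1L]
  if (isTRUE(params$identity)) {
    for (o in seq_len(dim(Wm)[1L]))
      Wm[o, o, 2L, 2L] <- Wm[o, o, 2L, 2L] + 1
  }
  params$W_merged <- Wm
  params$b_merged <- ag_value(params$conv3$b) + ag_value(params$conv1$b)
  params
}

#' AIFI parameters (deformable attention + FFN with layer norms)
#' @param dim hidden dim.
#' @param cfg a [deform_config()].
#' @param ffn_dim FFN inner width.
#' @param seed integer seed.
#' @return nested parameter list.
#' @export
aifi_params <- function(dim, cfg, ffn_dim = 4L * dim, seed = 0L) {
  with_seed(seed, list(
    dat = deform_attention_params(dim, cfg$heads, cfg$bias_table_side,
                                  seed = seed + 1L),
    ln1 = ln_param(dim),
    ln2 = ln_param(dim),
    ffn1 = linear_param(dim, ffn_dim),
    ffn2 = linear_param(ffn_dim, dim)
  ))
}

#' Intra-scale feature interaction on S5
#'
#' Flatten -> deformable attention (+ residual, layer norm) -> FFN
#' (+ residual, layer norm) -> reshape back to the S5 spatial shape. S3 and
#' S4 never enter this operation.
#'
#' @param S5 node/array `(b, dim, h, w)` with square spatial extent.
#' @param params from [aifi_params()].
#' @param cfg the [deform_config()] used for the attention.
#' @return `ag_node` shaped like `S5`.
#' @export
aifi <- function(S5, params, cfg) {
  S5 <- as_ag(S5)
  d <- dim(S5$value)
  if (d[3L] != d[4L]) stop("aifi expects a square S5 plane")
  att <- deformable_attention_forward(S5, params$dat, cfg)
  bsz <- d[1L]
  outs <- vector("list", bsz)
  for (i in seq_len(bsz)) {
    t0 <- fmap_tokens(S5, i)
    t1 <- ag_layernorm(ag_add(t0, fmap_tokens(att, i)),
                       params$ln1$gamma, params$ln1$beta)
    ff <- ag_linear(ag_relu(ag_linear(t1, params$ffn1$W, params$ffn1$b)),
                    params$ffn2$W, params$ffn2$b)
    t2 <- ag_layernorm(ag_add(t1, ff), params$ln2$gamma, params$ln2$beta)
    outs[[i]] <- tokens_fmap(t2, d[3L], d[4L])
  }
  if (bsz == 1L) outs[[1L]] else ag_stack_batch(outs)
}

# one CCFM fusion unit: concat two same-size maps -> 1x1 conv -> ReLU ->
# n RepBlocks
fusion_params <- function(hidden, n_rep = 3L, seed = 0L) {
  with_seed(seed, {
    list(reduce = conv_param(hidden, 2L * hidden, 1L),
         reps = lapply(seq_len(n_rep), function(j)
           repblock_params(hidden, hidden, seed = seed + j)))
  })
}

fusion_forward <- function(a, b, params) {
  h <- ag_relu(ag_conv2d(ag_cat_channels(list(a, b)), params$reduce$W,
                         params$reduce$b, stride = 1L, pad = 0L))
  for (rp in params$reps) h <- repblock_forward(h, rp, "train")
  h
}

#' Hybrid-encoder configuration
#' @param hidden_dim common channel width of the three scales.
#' @param heads,r,s,bias_enabled,bias_table_side deformable-attention
#'   settings for AIFI.
#' @param ffn_dim AIFI FFN inner width.
#' @param n_repblocks RepBlocks per fusion unit.
#' @param seed integer seed.
#' @return an `encoder_config` list.
#' @export
encoder_config <- function(hidden_dim = 256L, heads = 8L, r = 1L, s = 0.2,
                           bias_enabled = TRUE, bias_table_side = 31L,
                           ffn_dim = 2L * hidden_dim, n_repblocks = 3L,
                           seed = 0L) {
  structure(list(hidden_dim = as.integer(hidden_dim),
                 dat = deform_config(hidden_dim, heads, r, s, bias_enabled,
                                     bias_table_side),
                 ffn_dim = as.integer(ffn_dim),
                 n_repblocks = as.integer(n_repblocks),
                 seed = as.integer(seed)),
            class = "encoder_config")
}

#' Build the hybrid encoder
#' @param in_channels integer vector: channels of the incoming S3, S4, S5.
#' @param cfg an [encoder_config()].
#' @return an `encoder` module list.
#' @export
build_encoder <- function(in_channels, cfg = encoder_config()) {
  hd <- cfg$hidden_dim
  params <- with_seed(cfg$seed, list(
    proj = lapply(1:3, function(s) conv_param(hd, in_channels[s], 1L)),
    aifi = aifi_params(hd, cfg$dat, cfg$ffn_dim, seed = cfg$seed + 10L),
    td4 = fusion_params(hd, cfg$n_repblocks, seed = cfg$seed + 20L),
    td3 = fusion_params(hd, cfg$n_repblocks, seed = cfg$seed + 30L),
    bu4 = fusion_params(hd, cfg$n_repblocks, seed = cfg$seed + 40L),
    bu5 = fusion_params(hd, cfg$n_repblocks, seed = cfg$seed + 50L),
    down3 = conv_param(hd, hd, 3L),
    down4 = conv_param(hd, hd, 3L)
  ))
  structure(list(cfg = cfg, params = params), class = "encoder")
}

#' Cross-scale feature fusion (CCFM)
#'
#' Top-down pathway (nearest-neighbour x2 upsample, concat, RepBlock
#' fusion) followed by a bottom-up pathway (stride-2 conv downsample,
#' concat, fusion); where the two pathways meet the maps are combined by
#' element-wise addition. Inputs must already share the hidden channel
#' width.
#'
#' @param S3,S4,S5_aifi nodes at strides 8/16/32, `hidden_dim` channels.
#' @param params encoder parameter list (uses `td*`, `bu*`, `down*`).
#' @return list of three fused `ag_node`s at the input spatial sides.
#' @export
ccfm <- function(S3, S4, S5_aifi, params) {
  P5 <- as_ag(S5_aifi)
  P4 <- fusion_forward(ag_upsample2(P5), as_ag(S4), params$td4)
  P3 <- fusion_forward(ag_upsample2(P4), as_ag(S3), params$td3)
  N3 <- P3
  N4 <- fusion_forward(ag_conv2d(N3, params$down3$W, params$down3$b,
                                 stride = 2L, pad = 1L), P4, params$bu4)
  N5 <- fusion_forward(ag_conv2d(N4, params$down4$W, params$down4$b,
                                 stride = 2L, pad = 1L), P5, params$bu5)
  list(S3 = N3, S4 = ag_add(N4, P4), S5 = ag_add(N5, P5))
}

#' Run the hybrid encoder
#' @param enc an `encoder` from [build_encoder()].
#' @param feats list with `S3`, `S4`, `S5` backbone outputs.
#' @return list of three fused maps at `hidden_dim` channels.
#' @export
encoder_forward <- function(enc, feats) {
  p <- enc$params
  proj <- lapply(1:3, function(s)
    ag_conv2d(as_ag(feats[[s]]), p$proj[[s]]$W, p$proj[[s]]$b,
              stride = 1L, pad = 0L))
  S5a <- aifi(proj[[3L]], p$aifi, enc$cfg$dat)
  ccfm(proj[[1L]], proj[[2L]], S5a, p)
}
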