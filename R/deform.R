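# Deformable attention (DAT-style): a uniform reference grid, bounded
# learned offsets Delta p = s * tanh(theta_offset(q)), bilinear sampling of
# keys/values at the deformed points, an interpolated relative-position
# bias, and scaled-dot-product multi-head attention over the sampled
# tokens. The key count is H_G * W_G (grid cells), independent of the query
# count, so spatial complexity stays linear.

#' Token/feature-map conversions
#'
#' A `(b, c, h, w)` feature map is flattened to per-image `(h*w, c)` token
#' matrices with rows in column-major (y-fastest) order; `tokens_fmap`
#' inverts the layout.
#'
#' @param x node/array `(b, c, h, w)` (for `fmap_tokens`) or node/matrix
#'   `(h*w, c)` (for `tokens_fmap`).
#' @param i batch index to extract.
#' @param h,w spatial extent.
#' @return `ag_node`: `(h*w, c)` tokens, or a `(1, c, h, w)` map.
#' @name tokens
NULL

#' @rdname tokens
#' @export
fmap_tokens <- function(x, i = 1L) {
  x <- as_ag(x)
  d <- dim(x$value)
  sl <- ag_node(array(x$value[i, , , ], d[-1L]), list(x),
                function(g) {
                  gx <- array(0, d)
                  gx[i, , , ] <- g
                  list(gx)
                }, x$requires_grad)
  # (c, h, w) -> (h*w, c), rows y-fastest
  ag_aperm(ag_reshape(sl, c(d[2L], d[3L] * d[4L])), c(2L, 1L))
}

#' @rdname tokens
#' @export
tokens_fmap <- function(x, h, w) {
  x <- as_ag(x)
  cc <- ncol(x$value)
  ag_reshape(ag_aperm(x, c(2L, 1L)), c(1L, cc, h, w))
}

#' Uniform reference grid of normalized coordinates
#'
#' Integer lattice `0..H_G-1` x `0..W_G-1` (with `H_G = H/r`) mapped per
#' axis by `u -> 2u/(H_G - 1) - 1`, so (-1,-1) is the top-left point and
#' (+1,+1) the bottom-right; a single-point axis maps to 0 (center).
#'
#' @param H,W feature-map extent.
#' @param r downsample factor; must divide both `H` and `W`.
#' @return list with `points` (array `(H_G, W_G, 2)`, last dim = (x, y)),
#'   `flat` (matrix `(H_G*W_G, 2)` in y-fastest order), `H_G`, `W_G`, `r`.
#' @export
make_reference_grid <- function(H, W, r = 1L) {
  if (H %% r != 0L || W %% r != 0L)
    stop("r = ", r, " must divide H = ", H, " and W = ", W)
  H_G <- H %/% r; W_G <- W %/% r
  axis <- function(n) if (n == 1L) 0 else 2 * (seq_len(n) - 1) / (n - 1) - 1
  gx <- axis(W_G); gy <- axis(H_G)
  pts <- array(0, c(H_G, W_G, 2L))
  pts[, , 1L] <- matrix(gx, H_G, W_G, byrow = TRUE)
  pts[, , 2L] <- matrix(gy, H_G, W_G)
  flat <- cbind(as.vector(pts[, , 1L]), as.vector(pts[, , 2L]))
  list(points = pts, flat = flat, H_G = as.integer(H_G),
       W_G = as.integer(W_G), r = as.integer(r))
}

#' Parameters of one deformable-attention layer
#' @param dim token dimension (divisible by `heads`).
#' @param heads head count.
#' @param bias_table_side side of the learnable relative-position bias
#'   table (one table per head); ignored when the bias is disabled.
#' @param seed integer seed.
#' @return nested list of `ag_param` leaves.
#' @export
deform_attention_params <- function(dim, heads = 8L, bias_table_side = 31L,
                                    seed = 0L) {
  with_seed(seed, {
    list(
      Wq = linear_param(dim, dim),
      Wk = linear_param(dim, dim),
      Wv = linear_param(dim, dim),
      Wo = linear_param(dim, dim),
      # zero-initialized offset head: sampling starts at the reference grid
      offset = list(W = ag_param(matrix(0, dim, 2L)),
                    b = ag_param(numeric(2L))),
      bias_tables = lapply(seq_len(heads), function(m)
        ag_param(matrix(0, bias_table_side, bias_table_side)))
    )
  })
}

#' Bounded sampling offsets from query features
#'
#' `Delta p = s * tanh(theta_offset(q))`: one linear projection per grid
#' cell applied to that cell's (pooled) query feature, squashed by `tanh`
#' and scaled by the amplitude `s`, so no offset can exceed `s`.
#'
#' @param q node/matrix `(n_cells, dim)` of per-cell query features.
#' @param offset_params list with `W` (`dim x 2`) and `b` (length 2).
#' @param s positive offset amplitude (normalized units).
#' @return `ag_node` `(n_cells, 2)` of offsets.
#' @export
compute_offsets <- function(q, offset_params, s) {
  if (s <= 0) stop("offset amplitude s must be positive")
  ag_scale(ag_tanh(ag_linear(q, offset_params$W, offset_params$b)), s)
}

#' Bilinear sampling of a token matrix at normalized coordinates
#'
#' Thin public wrapper over the tape op: samples `(h*w, c)` tokens at
#' `(n, 2)` normalized coordinates ((-1,-1) = top-left pixel center,
#' out-of-range clamped to the border) with 4-neighbour interpolation.
#'
#' @param x node/matrix `(H*W, C)` in y-fastest order.
#' @param coords node/matrix `(n, 2)` of normalized (x, y).
#' @param H,W spatial extent.
#' @return `ag_node` `(n, C)`.
#' @export
bilinear_sample <- function(x, coords, H, W) ag_bilinear(x, coords, H, W)

#' Interpolated relative-position bias
#'
#' For every query/key pair the relative displacement `p_k - p_q` (range
#' `[-2, 2]` per axis for normalized positions) is rescaled to `[-1, 1]`
#' and used as a continuous lookup coordinate into the learnable bias
#' table, via the same bilinear kernel as feature sampling.
#'
#' @param table node/matrix (square bias table `B-hat`).
#' @param p_q `(n_q, 2)` matrix of query positions (normalized, constant).
#' @param p_k node/matrix `(n_k, 2)` of key positions (may carry gradients
#'   from the offset network).
#' @return `ag_node` `(n_q, n_k)` bias matrix.
#' @export
relative_position_bias <- function(table, p_q, p_k) {
  table <- as_ag(table)
  p_k <- as_ag(p_k)
  S <- nrow(table$value)
  nq <- nrow(p_q); nk <- nrow(p_k$value)
  # pairwise displacement, query-major rows: row (i, j) at i + (j-1)*nq
  pk_rep <- ag_rows(p_k, rep(seq_len(nk), each = nq))
  pq_rep <- p_q[rep(seq_len(nq), times = nk), , drop = FALSE]
  disp <- ag_scale(ag_sub(pk_rep, pq_rep), 0.5)   # [-2,2] -> [-1,1]
  tab_tokens <- ag_reshape(table, c(S * S, 1L))
  vals <- ag_bilinear(tab_tokens, disp, S, S)
  ag_reshape(vals, c(nq, nk))
}

#' Deformable-attention configuration
#' @param dim token dimension.
#' @param heads head count (`dim %% heads == 0`).
#' @param r reference-grid downsample factor.
#' @param s offset amplitude in normalized units.
#' @param bias_enabled use the interpolated relative-position bias.
#' @param bias_table_side bias-table side.
#' @return a `deform_config` list.
#' @export
deform_config <- function(dim, heads = 8L, r = 1L, s = 2 / 10,
                          bias_enabled = TRUE, bias_table_side = 31L) {
  if (dim %% heads != 0L) stop("dim must be divisible by heads")
  structure(list(dim = as.integer(dim), heads = as.integer(heads),
                 r = as.integer(r), s = s,
                 bias_enabled = isTRUE(bias_enabled),
                 bias_table_side = as.integer(bias_table_side)),
            class = "deform_config")
}

# average-pool tokens (h*w, c) onto the r-downsampled grid -> (H_G*W_G, c)
grid_pool_matrix <- function(H, W, r) {
  if (r == 1L) return(NULL)
  H_G <- H %/% r; W_G <- W %/% r
  P <- matrix(0, H_G * W_G, H * W)
  for (gx in seq_len(W_G)) for (gy in seq_len(H_G)) {
    cell <- gy + (gx - 1L) * H_G
    ys <- (gy - 1L) * r + seq_len(r)
    xs <- (gx - 1L) * r + seq_len(r)
    P[cell, as.vector(outer(ys, (xs - 1L) * H, "+"))] <- 1 / (r * r)
  }
  P
}

#' Deformable attention over one feature map
#'
#' Queries come from every pixel (`q = x W_q`); keys and values are
#' computed from features sampled at `p + Delta p` (reference grid plus
#' bounded learned offsets); each head applies
#' `softmax(q k~' / sqrt(d) + B~) v~`, heads are concatenated and passed
#' through the output projection.
#'
#' @param x node/array `(b, dim, h, w)`.
#' @param params from [deform_attention_params()].
#' @param cfg a [deform_config()].
#' @param return_internals also return per-image offsets and attention
#'   matrices (used by tests).
#' @return `ag_node` shaped like `x` (plus internals if requested).
#' @export
deformable_attention_forward <- function(x, params, cfg,
                                         return_internals = FALSE) {
  x <- as_ag(x)
  d <- dim(x$value)
  bsz <- d[1L]; H <- d[3L]; W <- d[4L]
  if (d[2L] != cfg$dim) stop("channel count must equal cfg$dim")
  grid <- make_reference_grid(H, W, cfg$r)
  P <- grid_pool_matrix(H, W, cfg$r)
  pix <- make_reference_grid(H, W, 1L)$flat    # query positions, all pixels
  outs <- vector("list", bsz)
  internals <- vector("list", bsz)
  for (i in seq_len(bsz)) {
    X <- fmap_tokens(x, i)                     # (hw, dim)
    q <- ag_linear(X, params$Wq$W, params$Wq$b)
    qg <- if (is.null(P)) q else ag_matmul(ag_const(P), q)
    dp <- compute_offsets(qg, params$offset, cfg$s)
    coords <- ag_add(dp, ag_const(grid$flat))
    xt <- ag_bilinear(X, coords, H, W)         # (ng, dim) sampled tokens
    k <- ag_linear(xt, params$Wk$W, params$Wk$b)
    v <- ag_linear(xt, params$Wv$W, params$Wv$b)
    biases <- if (cfg$bias_enabled)
      lapply(params$bias_tables, relative_position_bias, p_q = pix,
             p_k = coords)
    else NULL
    z <- ag_linear(ag_mha_fused(q, k, v, cfg$heads, biases = biases),
                   params$Wo$W, params$Wo$b)
    outs[[i]] <- tokens_fmap(z, H, W)
    if (return_internals)
      internals[[i]] <- list(offsets = dp, coords = coords)
  }
  out <- if (bsz == 1L) outs[[1L]] else ag_stack_batch(outs)
  if (return_internals) list(out = out, internals = internals) else out
}

# stack a list of (1, c, h, w) nodes into (b, c, h, w)
ag_stack_batch <- function(xs) {
  d <- dim(xs[[1L]]$value)
  bsz <- length(xs)
  out <- array(0, c(bsz, d[2L], d[3L], d[4L]))
  for (i in seq_len(bsz)) out[i, , , ] <- xs[[i]]$value
  backward <- function(g) lapply(seq_len(bsz), function(i)
    array(g[i, , , ], c(1L, d[2L], d[3L], d[4L])))
  ag_node(out, xs, backward,
          any(vapply(xs, function(x) x$requires_grad, TRUE)))
}
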