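# DETR-style detector head: IoU-aware selection of decoder queries from the
# encoder memory, denoising query groups built from noised ground truth, a
# decoder with multi-scale deformable cross-attention (each query samples a
# few points per scale around its own box center), Hungarian bipartite
# matching, and the combined classification + L1 + IACD-IoU training loss.
# Detection is end-to-end: a score threshold on the final queries, no NMS.

# ---- assignment ------------------------------------------------------------

#' Minimum-cost one-to-one assignment (Jonker-Volgenant)
#'
#' Shortest-augmenting-path solver with dual potentials, O(n^2 m). Solves
#' the rectangular problem by assigning every row when `nrow <= ncol`
#' (transposing internally otherwise).
#'
#' @param cost numeric cost matrix (finite).
#' @return list with `row` and `col` index vectors of the matched pairs and
#'   `cost`, the total assignment cost.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  if (!all(is.finite(cost))) stop("assignment cost must be finite")
  transposed <- FALSE
  if (nrow(cost) > ncol(cost)) {
    cost <- t(cost)
    transposed <- TRUE
  }
  n <- nrow(cost); m <- ncol(cost)
  u <- numeric(n)
  v <- numeric(m + 1L)          # index 1 is the virtual column
  p <- integer(m + 1L)          # p[j]: row assigned to column j-1 (0 none)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      for (j in which(!used[-1L]) + 1L) {
        cur <- cost[i0, j - 1L] - u[i0] - v[j]
        if (cur < minv[j]) {
          minv[j] <- cur
          way[j] <- j0
        }
        if (minv[j] < delta) {
          delta <- minv[j]
          j1 <- j
        }
      }
      for (j in seq_len(m + 1L)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  row_of_col <- p[-1L]
  cols <- which(row_of_col > 0L)
  rows <- row_of_col[cols]
  total <- sum(cost[cbind(rows, cols)])
  if (transposed) list(row = cols, col = rows, cost = total)
  else list(row = rows, col = cols, cost = total)
}

#' Hungarian matching of predictions to ground truth
#'
#' Pair cost is `lambda_cls * (-score of the gt class) + lambda_L1 *
#' ||box - gt||_1 + lambda_iou * (1 - IACD-IoU)`; the minimum-cost
#' one-to-one assignment covers every ground truth.
#'
#' @param pred_boxes matrix/data frame `(n_pred, 4)` of `cx, cy, w, h`
#'   (normalized).
#' @param pred_scores matrix `(n_pred, n_classes)` of class probabilities.
#' @param gt_boxes matrix/data frame `(n_gt, 4)`.
#' @param gt_classes integer class ids (1-based).
#' @param weights named vector with `cls`, `l1`, `iou` (DETR-family
#'   convention `c(2, 5, 2)`).
#' @param ratio interior-emphasis ratio of the IACD-IoU term.
#' @return list `pred` (matched prediction index per gt), `gt`, `cost`.
#' @export
hungarian_match <- function(pred_boxes, pred_scores, gt_boxes, gt_classes,
                            weights = c(cls = 2, l1 = 5, iou = 2),
                            ratio = 0.7) {
  pb <- as.matrix(as.data.frame(pred_boxes))[, 1:4, drop = FALSE]
  gb <- as.matrix(as.data.frame(gt_boxes))[, 1:4, drop = FALSE]
  np <- nrow(pb); ng <- nrow(gb)
  if (ng == 0L) return(list(pred = integer(0), gt = integer(0), cost = 0))
  ip <- rep(seq_len(np), times = ng)
  ig <- rep(seq_len(ng), each = np)
  P <- pb[ip, , drop = FALSE]
  G <- gb[ig, , drop = FALSE]
  l1 <- rowSums(abs(P - G))
  ia <- iacd_iou_mat(G, P, ratio)
  cls <- -as.matrix(pred_scores)[cbind(ip, gt_classes[ig])]
  cost <- matrix(weights[["cls"]] * cls + weights[["l1"]] * l1 +
                   weights[["iou"]] * (1 - ia), np, ng)
  a <- solve_assignment(cost)
  list(pred = a$row, gt = a$col, cost = a$cost)
}

# ---- query selection & denoising ------------------------------------------

#' IoU-aware query selection
#'
#' Ranks encoder tokens by their maximum class confidence (the confidence
#' head is supervised toward the IoU of each token's predicted box during
#' training, which is what makes the scores IoU-aware) and takes the top
#' `k`; ties break by ascending token index.
#'
#' @param scores matrix `(n_tokens, n_classes)` of class probabilities.
#' @param k query budget (default 300); effective count is
#'   `min(k, n_tokens)`.
#' @return integer vector of selected token indices, best first.
#' @export
iou_aware_query_select <- function(scores, k = 300L) {
  smax <- apply(as.matrix(scores), 1L, max)
  ord <- order(-smax, seq_along(smax))
  ord[seq_len(min(k, length(smax)))]
}

#' Denoising query groups from ground truth
#'
#' Per group, each ground-truth label is flipped to a uniformly random
#' *other* class with probability `label_flip_p`, and each of the four box
#' coordinates is jittered uniformly within `+/- box_noise_scale` times the
#' corresponding box side (w for cx and w, h for cy and h). Deterministic
#' for a fixed seed.
#'
#' @param gt_boxes data frame/matrix `(n, 4)` `cx, cy, w, h` (normalized).
#' @param gt_classes integer labels (1-based).
#' @param n_classes total class count.
#' @param label_flip_p flip probability.
#' @param box_noise_scale jitter bound as a fraction of the box side.
#' @param n_groups number of groups.
#' @param seed integer seed.
#' @return list of groups: each has `boxes`, `classes`, `group`.
#' @export
add_denoising_noise <- function(gt_boxes, gt_classes, n_classes,
                                label_flip_p = 0.5, box_noise_scale = 0.4,
                                n_groups = 5L, seed = 0L) {
  gb <- as.matrix(as.data.frame(gt_boxes))[, 1:4, drop = FALSE]
  n <- nrow(gb)
  with_seed(seed, lapply(seq_len(n_groups), function(g) {
    cls <- gt_classes
    if (n_classes > 1L) {
      flip <- stats::runif(n) < label_flip_p
      if (any(flip)) {
        cls[flip] <- vapply(cls[flip], function(c0)
          sample(setdiff(seq_len(n_classes), c0), 1L), 1L)
      }
    }
    jit <- matrix(stats::runif(4L * n, -1, 1), n, 4L) * box_noise_scale *
      gb[, c(3L, 4L, 3L, 4L), drop = FALSE]
    nb <- gb + jit
    nb[, 3:4] <- pmax(nb[, 3:4, drop = FALSE], 1e-3)
    nb[, 1:2] <- pmin(pmax(nb[, 1:2, drop = FALSE], 1e-3), 1 - 1e-3)
    list(boxes = nb, classes = cls, group = g)
  }))
}

#' Decoder self-attention mask for denoising training
#'
#' Square logical matrix (TRUE = blocked) over `n_match + n_groups * n_dn`
#' queries: denoising groups never see each other, and matching queries
#' never see any denoising query (so ground-truth information cannot leak
#' into the matched predictions).
#'
#' @param n_match number of matching queries.
#' @param group_sizes integer vector of denoising group sizes.
#' @return logical matrix.
#' @export
denoising_attn_mask <- function(n_match, group_sizes) {
  tot <- n_match + sum(group_sizes)
  blocked <- matrix(FALSE, tot, tot)
  if (!length(group_sizes) || sum(group_sizes) == 0L) return(blocked)
  ends <- n_match + cumsum(group_sizes)
  starts <- ends - group_sizes + 1L
  dn_all <- (n_match + 1L):tot
  if (n_match > 0L) blocked[seq_len(n_match), dn_all] <- TRUE
  for (g in seq_along(group_sizes)) {
    idx <- starts[g]:ends[g]
    blocked[idx, setdiff(dn_all, idx)] <- TRUE
  }
  blocked
}

# ---- decoder ---------------------------------------------------------------

mha_params <- function(dim, seed = 0L) {
  with_seed(seed, list(Wq = linear_param(dim, dim), Wk = linear_param(dim, dim),
                       Wv = linear_param(dim, dim), Wo = linear_param(dim, dim)))
}

mha_forward <- function(q_in, k_in, v_in, params, heads, mask = NULL) {
  q <- ag_linear(q_in, params$Wq$W, params$Wq$b)
  k <- ag_linear(k_in, params$Wk$W, params$Wk$b)
  v <- ag_linear(v_in, params$Wv$W, params$Wv$b)
  mnum <- if (is.null(mask)) NULL else ifelse(mask, -1e9, 0)
  ag_linear(ag_mha_fused(q, k, v, heads, mask = mnum),
            params$Wo$W, params$Wo$b)
}

#' Decoder configuration
#' @param dim hidden dim (matches the encoder hidden dim).
#' @param n_classes class count.
#' @param n_layers decoder layers.
#' @param heads self-attention heads.
#' @param n_queries matching-query budget.
#' @param ffn_dim FFN inner width.
#' @param n_points sampling points per scale in the multi-scale deformable
#'   cross-attention.
#' @param s offset amplitude of the cross-attention sampling (normalized
#'   units, bounds how far a query can look from its own box center).
#' @param seed integer seed.
#' @return a `decoder_config` list.
#' @export
decoder_config <- function(dim = 64L, n_classes = 1L, n_layers = 2L,
                           heads = 8L, n_queries = 300L,
                           ffn_dim = 2L * dim, n_points = 4L, s = 0.5,
                           seed = 0L) {
  structure(list(dim = as.integer(dim), n_classes = as.integer(n_classes),
                 n_layers = as.integer(n_layers), heads = as.integer(heads),
                 n_queries = as.integer(n_queries),
                 ffn_dim = as.integer(ffn_dim),
                 n_points = as.integer(n_points), s = s,
                 seed = as.integer(seed)),
            class = "decoder_config")
}

decoder_params <- function(cfg) {
  with_seed(cfg$seed, {
    K <- cfg$n_points
    layers <- lapply(seq_len(cfg$n_layers), function(l) with_seed(
      cfg$seed + 100L * l, list(
        self = mha_params(cfg$dim, seed = cfg$seed + 100L * l + 1L),
        # multi-scale deformable cross-attention: sampling offsets start
        # near the query's box center (zero weights, small spread in the
        # bias so the K points per scale separate)
        samp_off = list(W = ag_param(matrix(0, cfg$dim, 3L * K * 2L)),
                        b = ag_param(stats::rnorm(3L * K * 2L, sd = 0.3))),
        samp_attn = linear_param(cfg$dim, 3L * K),
        Wv = lapply(1:3, function(s2) linear_param(cfg$dim, cfg$dim)),
        cross_o = linear_param(cfg$dim, cfg$dim),
        ln1 = ln_param(cfg$dim), ln2 = ln_param(cfg$dim),
        ln3 = ln_param(cfg$dim),
        ffn1 = linear_param(cfg$dim, cfg$ffn_dim),
        ffn2 = linear_param(cfg$ffn_dim, cfg$dim))))
    list(layers = layers,
         pos_emb = linear_param(4L, cfg$dim),
         label_emb = ag_param(matrix(stats::rnorm((cfg$n_classes + 1L) *
                                                    cfg$dim, sd = 0.02),
                                     cfg$n_classes + 1L, cfg$dim)),
         class_head = linear_param(cfg$dim, cfg$n_classes, gain = 0.1),
         box_head1 = linear_param(cfg$dim, cfg$dim),
         box_head2 = linear_param(cfg$dim, 4L, gain = 0.1))
  })
}

# multi-scale deformable cross-attention: each query samples n_points
# locations per scale around its own (current) box center, at content-
# predicted bounded offsets, and combines the sampled values with content-
# predicted softmax weights over all scale/point slots. Box-anchored
# sampling is what lets the decoder localize in few training steps;
# gradients flow into the offsets, the weights and the box logits.
decoder_cross_attention <- function(content_pos, coords_logit, memory, lp,
                                    cfg) {
  K <- cfg$n_points
  k_q <- nrow(ag_value(content_pos))
  # query centers in normalized [-1, 1] sampling coordinates
  ref <- ag_sub(ag_scale(ag_sigmoid(ag_cols(coords_logit, 1:2)), 2), 1)
  offs <- ag_scale(ag_tanh(ag_linear(content_pos, lp$samp_off$W,
                                     lp$samp_off$b)), cfg$s)
  A <- ag_softmax(ag_linear(content_pos, lp$samp_attn$W, lp$samp_attn$b))
  z <- NULL
  for (s2 in 1:3) {
    mem <- memory[[s2]]
    pts <- lapply(seq_len(K), function(kpt) {
      cols <- (s2 - 1L) * K * 2L + (kpt - 1L) * 2L + 1:2
      ag_add(ref, ag_cols(offs, cols))
    })
    coords <- ag_rbind(pts)                       # (k*K, 2), point-major
    xt <- ag_bilinear(mem$tokens, coords, mem$H, mem$W)
    v <- ag_linear(xt, lp$Wv[[s2]]$W, lp$Wv[[s2]]$b)
    for (kpt in seq_len(K)) {
      vi <- ag_rows(v, (kpt - 1L) * k_q + seq_len(k_q))
      wi <- ag_cols(A, (s2 - 1L) * K + kpt)
      term <- ag_row_scale(vi, wi)
      z <- if (is.null(z)) term else ag_add(z, term)
    }
  }
  ag_linear(z, lp$cross_o$W, lp$cross_o$b)
}

#' Decoder forward pass (one image)
#'
#' Each layer runs masked self-attention over the queries, deformable
#' cross-attention into the multi-scale memory, and an FFN (post-layer-norm
#' residuals); the shared box head refines the coordinates additively in
#' logit space, and auxiliary class/box outputs are emitted at every layer.
#'
#' @param content node/matrix `(k, dim)` initial query content.
#' @param coords_logit node/matrix `(k, 4)` initial box logits.
#' @param memory list of 3 scales, each `list(tokens, H, W)`.
#' @param params from `decoder_params()`.
#' @param cfg a [decoder_config()].
#' @param mask optional logical self-attention mask (TRUE = blocked).
#' @return list of per-layer outputs: `logits` (k, n_classes) and `boxes`
#'   (`ag_node`, (k, 4) in (0,1)).
#' @export
decoder_forward <- function(content, coords_logit, memory, params, cfg,
                            mask = NULL) {
  content <- as_ag(content)
  coords_logit <- as_ag(coords_logit)
  outputs <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    lp <- params$layers[[l]]
    pos <- ag_linear(ag_sigmoid(coords_logit), params$pos_emb$W,
                     params$pos_emb$b)
    cp <- ag_add(content, pos)
    sa <- mha_forward(cp, cp, content, lp$self, cfg$heads, mask)
    content <- ag_layernorm(ag_add(content, sa), lp$ln1$gamma, lp$ln1$beta)
    cp <- ag_add(content, pos)
    ca <- decoder_cross_attention(cp, coords_logit, memory, lp, cfg)
    content <- ag_layernorm(ag_add(content, ca), lp$ln2$gamma, lp$ln2$beta)
    ff <- ag_linear(ag_relu(ag_linear(content, lp$ffn1$W, lp$ffn1$b)),
                    lp$ffn2$W, lp$ffn2$b)
    content <- ag_layernorm(ag_add(content, ff), lp$ln3$gamma, lp$ln3$beta)
    delta <- ag_linear(ag_relu(ag_linear(content, params$box_head1$W,
                                         params$box_head1$b)),
                       params$box_head2$W, params$box_head2$b)
    coords_logit <- ag_add(coords_logit, delta)
    logits <- ag_linear(content, params$class_head$W, params$class_head$b)
    outputs[[l]] <- list(logits = logits, boxes = ag_sigmoid(coords_logit))
  }
  outputs
}
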