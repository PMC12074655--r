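# Independent oracles used across the suite. Everything here is deliberately
# naive (double loops, enumeration) and never calls the implementation path
# it is used to check.

# naive dense 2-D convolution, cross-correlation with zero padding
naive_conv2d <- function(x, W, b = NULL, stride = 1, pad = 1) {
  d <- dim(x); dw <- dim(W)
  bsz <- d[1]; cin <- d[2]; h <- d[3]; w <- d[4]
  cout <- dw[1]; kh <- dw[3]; kw <- dw[4]
  oh <- (h + 2 * pad - kh) %/% stride + 1
  ow <- (w + 2 * pad - kw) %/% stride + 1
  xp <- array(0, c(bsz, cin, h + 2 * pad, w + 2 * pad))
  xp[, , pad + seq_len(h), pad + seq_len(w)] <- x
  out <- array(0, c(bsz, cout, oh, ow))
  for (i in seq_len(bsz)) for (o in seq_len(cout))
    for (oy in seq_len(oh)) for (ox in seq_len(ow)) {
      acc <- if (is.null(b)) 0 else b[o]
      for (ci in seq_len(cin)) for (ky in seq_len(kh)) for (kx in seq_len(kw))
        acc <- acc + xp[i, ci, (oy - 1) * stride + ky, (ox - 1) * stride + kx] *
          W[o, ci, ky, kx]
      out[i, o, oy, ox] <- acc
    }
  out
}

# brute-force minimum assignment cost by permutation enumeration
brute_assignment_cost <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) return(brute_assignment_cost(t(cost)))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  best <- Inf
  for (p in perms(seq_len(m))) {
    cst <- sum(cost[cbind(seq_len(n), p[seq_len(n)])])
    if (cst < best) best <- cst
  }
  best
}

# literal cell-by-cell rasterized IoU (the oracle-of-the-oracle)
naive_raster_iou <- function(a, b, step) {
  lo_x <- min(a$bl, b$bl) - step; hi_x <- max(a$br, b$br) + step
  lo_y <- min(a$bt, b$bt) - step; hi_y <- max(a$bb, b$bb) + step
  ks <- seq(floor(lo_x / step), ceiling(hi_x / step))
  xs <- (ks - 0.5) * step
  ks <- seq(floor(lo_y / step), ceiling(hi_y / step))
  ys <- (ks - 0.5) * step
  both <- 0; either <- 0
  for (x in xs) for (y in ys) {
    ina <- x >= a$bl && x <= a$br && y >= a$bt && y <= a$bb
    inb <- x >= b$bl && x <= b$br && y >= b$bt && y <= b$bb
    if (ina && inb) both <- both + 1
    if (ina || inb) either <- either + 1
  }
  if (either == 0) 0 else both / either
}

# dense reference multi-head attention (plain R, no tape)
reference_attention <- function(X, pars, heads) {
  lin <- function(M, p) sweep(M %*% ag_value(p$W), 2, ag_value(p$b), "+")
  q <- lin(X, pars$Wq); k <- lin(X, pars$Wk); v <- lin(X, pars$Wv)
  dim_ <- ncol(q); dh <- dim_ %/% heads
  z <- matrix(0, nrow(X), dim_)
  for (m in seq_len(heads)) {
    idx <- ((m - 1) * dh + 1):(m * dh)
    s <- q[, idx] %*% t(k[, idx]) / sqrt(dh)
    A <- exp(s - apply(s, 1, max)); A <- A / rowSums(A)
    z[, idx] <- A %*% v[, idx]
  }
  lin(z, pars$Wo)
}

# central-difference gradient of f (scalar-valued) wrt param node p
fd_grad <- function(f, p, idx = seq_along(p$value), eps = 1e-5) {
  g <- numeric(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    v0 <- p$value[i]
    p$value[i] <- v0 + eps; fp <- ag_value(f())
    p$value[i] <- v0 - eps; fm <- ag_value(f())
    p$value[i] <- v0
    g[j] <- (fp - fm) / (2 * eps)
  }
  g
}

# exhaustive threshold-sweep average precision (independent of the
# implementation's ranking-based computation)
sweep_ap <- function(dets, gts, iou_threshold) {
  n_gt <- nrow(gts)
  if (n_gt == 0 || nrow(dets) == 0) return(0)
  plain_iou <- function(a, b) {
    il <- max(a$cx - a$w / 2, b$cx - b$w / 2)
    ir <- min(a$cx + a$w / 2, b$cx + b$w / 2)
    it <- max(a$cy - a$h / 2, b$cy - b$h / 2)
    ib <- min(a$cy + a$h / 2, b$cy + b$h / 2)
    inter <- max(0, ir - il) * max(0, ib - it)
    inter / (a$w * a$h + b$w * b$h - inter)
  }
  pr_at <- function(thr) {
    keep <- dets[dets$score >= thr, , drop = FALSE]
    if (!nrow(keep)) return(c(0, 0))
    tp <- 0
    for (img in unique(gts$image_id)) for (cl in unique(gts$class_id)) {
      d1 <- keep[keep$image_id == img & keep$class_id == cl, , drop = FALSE]
      g1 <- gts[gts$image_id == img & gts$class_id == cl, , drop = FALSE]
      if (!nrow(d1) || !nrow(g1)) next
      d1 <- d1[order(-d1$score), , drop = FALSE]
      used <- logical(nrow(g1))
      for (i in seq_len(nrow(d1))) {
        ious <- vapply(seq_len(nrow(g1)), function(j)
          if (used[j]) -1 else plain_iou(d1[i, ], g1[j, ]), 1.0)
        j <- which.max(ious)
        if (ious[j] >= iou_threshold) { tp <- tp + 1; used[j] <- TRUE }
      }
    }
    c(tp / nrow(keep), tp / n_gt)
  }
  thrs <- sort(unique(dets$score))
  pr <- t(vapply(thrs, pr_at, c(1.0, 1.0)))
  prec <- pr[, 1]; rec <- pr[, 2]
  mean(vapply(seq(0, 1, by = 0.01), function(r) {
    sel <- rec >= r
    if (any(sel)) max(prec[sel]) else 0
  }, 1.0))
}

# small toy detector configuration shared by the training tests
toy_detector_config <- function(seed = 10L) {
  osdetr_config(
    input_side = 160L, n_classes = 1L,
    backbone = backbone_config(input_channels = 1L, stem_channels = 16L,
                               stage_channels = c(16L, 32L, 64L),
                               stage_depths = c(1L, 1L, 1L),
                               attention_reduction = 8L, seed = seed + 1L),
    encoder = encoder_config(hidden_dim = 64L, heads = 8L, r = 1L, s = 0.2,
                             bias_enabled = TRUE, bias_table_side = 15L,
                             ffn_dim = 128L, n_repblocks = 2L,
                             seed = seed + 2L),
    decoder = decoder_config(dim = 64L, n_classes = 1L, n_layers = 2L,
                             heads = 8L, n_queries = 50L, ffn_dim = 128L,
                             s = 0.2, seed = seed + 3L),
    seed = seed)
}
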