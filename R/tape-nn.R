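# Network-layer operations on the tape: 2-D convolution (im2col + BLAS,
# scatter-add backward through a cached sparse matrix), batch/layer
# normalization, bilinear grid sampling (differentiable in both the feature
# map and the sampling coordinates), nearest-neighbour upsampling, and
# feature-map plumbing. Feature maps are arrays with dim (b, c, h, w).

.conv_cache <- new.env(parent = emptyenv())

conv_plan <- function(cin, h, w, kh, kw, stride, pad) {
  key <- paste(cin, h, w, kh, kw, stride, pad, sep = "_")
  pl <- .conv_cache[[key]]
  if (!is.null(pl)) return(pl)
  hp <- h + 2L * pad; wp <- w + 2L * pad
  oh <- (hp - kh) %/% stride + 1L
  ow <- (wp - kw) %/% stride + 1L
  # flat index into a (cin, hp, wp) volume for every (output position, patch
  # element); rows ordered (oy fastest, then ox), cols ordered (ci, ky, kx)
  oy <- rep(seq_len(oh), times = ow)
  ox <- rep(seq_len(ow), each = oh)
  ci <- rep(seq_len(cin), times = kh * kw)
  ky <- rep(rep(seq_len(kh), each = cin), times = kw)
  kx <- rep(seq_len(kw), each = cin * kh)
  y0 <- (oy - 1L) * stride    # top-left of patch (0-based in padded coords)
  x0 <- (ox - 1L) * stride
  idx <- outer(seq_along(oy), seq_along(ci), function(r, c2) {
    ci[c2] + (y0[r] + ky[c2] - 1L) * cin + (x0[r] + kx[c2] - 1L) * cin * hp
  })
  npad <- cin * hp * wp
  scat <- Matrix::sparseMatrix(
    i = as.vector(idx),
    j = seq_along(idx),
    x = 1,
    dims = c(npad, length(idx))
  )
  pl <- list(hp = hp, wp = wp, oh = oh, ow = ow, idx = idx,
             idx_vec = as.vector(idx), idx_dim = dim(idx), scat = scat,
             npad = npad)
  .conv_cache[[key]] <- pl
  pl
}

pad_chw <- function(x_chw, cin, h, w, pad) {
  if (pad == 0L) return(x_chw)
  out <- array(0, c(cin, h + 2L * pad, w + 2L * pad))
  out[, (pad + 1L):(pad + h), (pad + 1L):(pad + w)] <- x_chw
  out
}

#' 2-D convolution on the tape
#'
#' Cross-correlation with zero padding, `floor((h + 2 pad - kh)/stride) + 1`
#' output side. Weight layout is `(out, in, kh, kw)`.
#'
#' @param x node/array `(b, c_in, h, w)`.
#' @param W node/array `(c_out, c_in, kh, kw)`.
#' @param b node/vector of length `c_out`, or `NULL`.
#' @param stride integer stride (1 or 2 in this package).
#' @param pad zero-padding on every side.
#' @return `ag_node` of shape `(b, c_out, oh, ow)`.
#' @export
ag_conv2d <- function(x, W, b = NULL, stride = 1L, pad = 1L) {
  x <- as_ag(x); W <- as_ag(W)
  xv <- x$value; wv <- W$value
  dx <- dim(xv); dw <- dim(wv)
  bsz <- dx[1L]; cin <- dx[2L]; h <- dx[3L]; w <- dx[4L]
  cout <- dw[1L]; kh <- dw[3L]; kw <- dw[4L]
  stopifnot(dw[2L] == cin)
  pl <- conv_plan(cin, h, w, kh, kw, as.integer(stride), as.integer(pad))
  wmat <- matrix(aperm(wv, c(2L, 3L, 4L, 1L)), cin * kh * kw, cout)
  npos <- nrow(pl$idx)
  cols <- vector("list", bsz)
  out <- array(0, c(bsz, cout, pl$oh, pl$ow))
  for (i in seq_len(bsz)) {
    xi <- pad_chw(array(xv[i, , , ], c(cin, h, w)), cin, h, w, pad)
    xc <- xi[pl$idx_vec]          # flat indexing (idx must not be a matrix
    dim(xc) <- pl$idx_dim         # here: R would read it as coordinates)
    cols[[i]] <- xc
    y <- xc %*% wmat                       # (oh*ow, cout)
    out[i, , , ] <- aperm(array(y, c(pl$oh, pl$ow, cout)), c(3L, 1L, 2L))
  }
  bn <- if (is.null(b)) NULL else as_ag(b)
  if (!is.null(bn))
    out <- out + array(rep(rep(bn$value, each = bsz), pl$oh * pl$ow), dim(out))
  parents <- list(x, W)
  if (!is.null(bn)) parents <- c(parents, list(bn))
  req <- x$requires_grad || W$requires_grad ||
    (!is.null(bn) && bn$requires_grad)
  backward <- function(g) {
    gwmat <- matrix(0, cin * kh * kw, cout)
    gx <- array(0, dx)
    gb_acc <- if (is.null(bn)) NULL else numeric(cout)
    for (i in seq_len(bsz)) {
      gi <- array(g[i, , , ], c(cout, pl$oh, pl$ow))
      gy <- matrix(aperm(gi, c(2L, 3L, 1L)), npos, cout)
      gwmat <- gwmat + crossprod(cols[[i]], gy)
      if (!is.null(gb_acc)) gb_acc <- gb_acc + colSums(gy)
      gcols <- gy %*% t(wmat)              # (oh*ow, ckk)
      gpad <- as.numeric(pl$scat %*% as.vector(gcols))
      gpad <- array(gpad, c(cin, pl$hp, pl$wp))
      gx[i, , , ] <- if (pad == 0L) gpad
        else gpad[, (pad + 1L):(pad + h), (pad + 1L):(pad + w)]
    }
    gW <- array(0, dw)
    gW[] <- aperm(array(gwmat, c(cin, kh, kw, cout)), c(4L, 1L, 2L, 3L))
    res <- list(gx, gW)
    if (!is.null(bn)) res <- c(res, list(gb_acc))
    res
  }
  ag_node(out, parents, backward, req)
}

#' Batch normalization over a (b, c, h, w) node
#'
#' Normalizes each channel over batch and space. In training mode batch
#' statistics are used and running statistics in `state` are updated; in
#' evaluation mode the running statistics are used.
#'
#' @param x node/array `(b, c, h, w)`.
#' @param gamma,beta nodes/vectors of length `c`.
#' @param state environment with `mean`, `var` (running statistics) and
#'   `momentum`; create with [bn_state()].
#' @param training logical.
#' @param eps variance floor.
#' @return `ag_node` shaped like `x`.
#' @export
ag_batchnorm <- function(x, gamma, beta, state, training = TRUE, eps = 1e-5) {
  x <- as_ag(x); gamma <- as_ag(gamma); beta <- as_ag(beta)
  xv <- x$value
  d <- dim(xv)
  bsz <- d[1L]; cc <- d[2L]; hw <- d[3L] * d[4L]
  n <- bsz * hw
  M <- xv; dim(M) <- c(bsz * cc, hw)       # rows (b, c) pairs, b fastest
  chan_mean <- function(Z) colMeans(matrix(rowSums(Z), bsz, cc)) / hw
  if (training) {
    mu <- chan_mean(M)
    va <- chan_mean(M * M) - mu * mu
    mom <- state$momentum
    state$mean <- mom * state$mean + (1 - mom) * mu
    state$var <- mom * state$var + (1 - mom) * va * n / max(n - 1, 1)
  } else {
    mu <- state$mean
    va <- state$var
  }
  ivar <- 1 / sqrt(va + eps)
  mu_bc <- rep(mu, each = bsz)             # per (b, c) row
  iv_bc <- rep(ivar, each = bsz)
  xhat <- (M - mu_bc) * iv_bc
  Y <- xhat * rep(gamma$value, each = bsz) + rep(beta$value, each = bsz)
  out <- Y; dim(out) <- d
  backward <- function(g) {
    G <- g; dim(G) <- c(bsz * cc, hw)
    rs <- function(Z) colSums(matrix(rowSums(Z), bsz, cc))
    dgamma <- rs(G * xhat)
    dbeta <- rs(G)
    dxhat <- G * rep(gamma$value, each = bsz)
    if (training) {
      dM <- iv_bc * (dxhat - rep(rs(dxhat) / n, each = bsz) -
                       xhat * rep(rs(dxhat * xhat) / n, each = bsz))
    } else {
      dM <- dxhat * iv_bc
    }
    gx <- dM; dim(gx) <- d
    list(gx, dgamma, dbeta)
  }
  ag_node(out, list(x, gamma, beta), backward,
          x$requires_grad || gamma$requires_grad || beta$requires_grad)
}

#' Running-statistics holder for [ag_batchnorm()]
#' @param c channel count.
#' @param momentum running-average momentum.
#' @return environment with `mean`, `var`, `momentum`.
#' @export
bn_state <- function(c, momentum = 0.9) {
  e <- new.env(parent = emptyenv())
  e$mean <- numeric(c)
  e$var <- rep(1, c)
  e$momentum <- momentum
  e
}

#' Layer normalization over matrix rows
#' @param x node/matrix `(n, d)`; each row is normalized.
#' @param gamma,beta nodes/vectors of length `d`.
#' @param eps variance floor.
#' @return `ag_node` shaped like `x`.
#' @export
ag_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_ag(x); gamma <- as_ag(gamma); beta <- as_ag(beta)
  v <- x$value
  d <- ncol(v)
  mu <- rowMeans(v)
  xc <- v - mu
  va <- rowMeans(xc * xc)
  ivar <- 1 / sqrt(va + eps)
  xhat <- xc * ivar
  out <- sweep(sweep(xhat, 2L, gamma$value, "*"), 2L, beta$value, "+")
  backward <- function(g) {
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    dxhat <- sweep(g, 2L, gamma$value, "*")
    dx <- ivar * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    list(dx, dgamma, dbeta)
  }
  ag_node(out, list(x, gamma, beta), backward,
          x$requires_grad || gamma$requires_grad || beta$requires_grad)
}

#' Differentiable bilinear sampling of a flattened feature map
#'
#' `x` holds one spatial map as a `(H*W, C)` matrix with rows ordered
#' y-fastest (flat index `iy + (ix-1)*H`, R's column-major order, as
#' produced by [fmap_tokens()]). `coords` are normalized to
#' `[-1, 1]` with (-1,-1) the top-left pixel center; out-of-range
#' coordinates are clamped to the border. Gradients flow to both the map
#' and the coordinates (zero where clamped).
#'
#' @param x node/matrix `(H*W, C)`.
#' @param coords node/matrix `(n, 2)` of normalized (x, y).
#' @param H,W spatial extent of the map.
#' @return `ag_node` of sampled features `(n, C)`.
#' @export
ag_bilinear <- function(x, coords, H, W) {
  x <- as_ag(x); coords <- as_ag(coords)
  xv <- x$value
  cv <- coords$value
  sx <- if (W > 1L) (W - 1) / 2 else 0
  sy <- if (H > 1L) (H - 1) / 2 else 0
  px <- (cv[, 1L] + 1) * sx + 1
  py <- (cv[, 2L] + 1) * sy + 1
  cx <- pmin(pmax(px, 1), W)
  cy <- pmin(pmax(py, 1), H)
  inx <- (px >= 1) & (px <= W)     # gradient passes only where not clamped
  iny <- (py >= 1) & (py <= H)
  x0 <- pmin(floor(cx), W - 1e-9); x0 <- pmax(1, floor(x0)); x1 <- pmin(x0 + 1, W)
  y0 <- pmin(floor(cy), H - 1e-9); y0 <- pmax(1, floor(y0)); y1 <- pmin(y0 + 1, H)
  wx <- cx - x0
  wy <- cy - y0
  k00 <- y0 + (x0 - 1) * H
  k01 <- y0 + (x1 - 1) * H
  k10 <- y1 + (x0 - 1) * H
  k11 <- y1 + (x1 - 1) * H
  w00 <- (1 - wy) * (1 - wx); w01 <- (1 - wy) * wx
  w10 <- wy * (1 - wx);       w11 <- wy * wx
  v00 <- xv[k00, , drop = FALSE]; v01 <- xv[k01, , drop = FALSE]
  v10 <- xv[k10, , drop = FALSE]; v11 <- xv[k11, , drop = FALSE]
  out <- v00 * w00 + v01 * w01 + v10 * w10 + v11 * w11
  backward <- function(g) {
    gx <- NULL
    if (x$requires_grad) {
      gx <- matrix(0, nrow(xv), ncol(xv))
      scat <- function(k, w) {
        agg <- rowsum(g * w, group = k)
        ids <- as.integer(rownames(agg))
        gx[ids, ] <<- gx[ids, , drop = FALSE] + agg
      }
      scat(k00, w00); scat(k01, w01); scat(k10, w10); scat(k11, w11)
    }
    gc2 <- NULL
    if (coords$requires_grad) {
      # d out / d wx and d out / d wy, then chain to normalized coords
      dwx <- rowSums(g * ((v01 - v00) * (1 - wy) + (v11 - v10) * wy))
      dwy <- rowSums(g * ((v10 - v00) * (1 - wx) + (v11 - v01) * wx))
      gc2 <- cbind(dwx * sx * inx, dwy * sy * iny)
    }
    list(gx, gc2)
  }
  ag_node(out, list(x, coords), backward,
          x$requires_grad || coords$requires_grad)
}

#' Nearest-neighbour 2x upsampling of a (b, c, h, w) node
#' @param x node/array `(b, c, h, w)`.
#' @return `ag_node` of shape `(b, c, 2h, 2w)`.
#' @export
ag_upsample2 <- function(x) {
  x <- as_ag(x)
  v <- x$value
  d <- dim(v)
  ri <- rep(seq_len(d[3L]), each = 2L)
  ci <- rep(seq_len(d[4L]), each = 2L)
  out <- v[, , ri, ci, drop = FALSE]
  backward <- function(g) {
    gx <- array(0, d)
    for (a in 1:2) for (b2 in 1:2) {
      gx <- gx + g[, , seq(a, 2L * d[3L], by = 2L),
                   seq(b2, 2L * d[4L], by = 2L), drop = FALSE]
    }
    list(gx)
  }
  ag_node(out, list(x), backward, x$requires_grad)
}

#' Concatenate (b, c, h, w) nodes along the channel axis
#' @param xs list of nodes with identical `(b, h, w)`.
#' @return `ag_node`.
#' @export
ag_cat_channels <- function(xs) {
  xs <- lapply(xs, as_ag)
  ds <- lapply(xs, function(x) dim(x$value))
  cs <- vapply(ds, `[`, 1L, 2L)
  d1 <- ds[[1L]]
  out <- array(0, c(d1[1L], sum(cs), d1[3L], d1[4L]))
  ends <- cumsum(cs); starts <- ends - cs + 1L
  for (i in seq_along(xs)) out[, starts[i]:ends[i], , ] <- xs[[i]]$value
  backward <- function(g) lapply(seq_along(xs), function(i)
    g[, starts[i]:ends[i], , , drop = FALSE])
  ag_node(out, xs, backward,
          any(vapply(xs, function(x) x$requires_grad, TRUE)))
}

#' Scale each channel of a (b, c, h, w) node by a (b, c) weight
#' @param x node/array `(b, c, h, w)`.
#' @param s node/matrix `(b, c)` broadcast over space.
#' @return `ag_node` shaped like `x`.
#' @export
ag_channel_scale <- function(x, s) {
  x <- as_ag(x); s <- as_ag(s)
  xv <- x$value; sv <- s$value
  d <- dim(xv)
  sfull <- array(sv, d)   # (b, c) recycles over the trailing h, w dims
  out <- xv * sfull
  backward <- function(g) {
    gs <- NULL
    if (s$requires_grad) {
      gm <- g * xv
      dim(gm) <- c(d[1L] * d[2L], d[3L] * d[4L])
      gs <- matrix(rowSums(gm), d[1L], d[2L])
    }
    list(g * sfull, gs)
  }
  ag_node(out, list(x, s), backward, x$requires_grad || s$requires_grad)
}

#' Reorder the channels of a (b, c, h, w) node by a fixed permutation
#' @param x node/array `(b, c, h, w)`.
#' @param perm integer permutation of `1:c`.
#' @return `ag_node` with channels `x[, perm, , ]`.
#' @export
ag_permute_channels <- function(x, perm) {
  x <- as_ag(x)
  inv <- order(perm)
  ag_node(x$value[, perm, , , drop = FALSE], list(x),
          function(g) list(g[, inv, , , drop = FALSE]), x$requires_grad)
}

# ---- parameter initialisation ---------------------------------------------

#' Seed-scoped evaluation
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state,
#' so library functions never perturb a user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

init_kaiming <- function(fan_in, dims) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

conv_param <- function(cout, cin, k, bias = TRUE) {
  p <- list(W = ag_param(init_kaiming(cin * k * k, c(cout, cin, k, k))))
  if (bias) p$b <- ag_param(numeric(cout))
  p
}

linear_param <- function(din, dout, gain = 1) {
  list(W = ag_param(matrix(stats::rnorm(din * dout,
                                        sd = gain * sqrt(2 / din)),
                           din, dout)),
       b = ag_param(numeric(dout)))
}

bn_param <- function(c) {
  list(gamma = ag_param(rep(1, c)), beta = ag_param(numeric(c)),
       state = bn_state(c))
}

ln_param <- function(d) {
  list(gamma = ag_param(rep(1, d)), beta = ag_param(numeric(d)))
}

# collect every ag_param inside a nested module list, named by path
collect_params <- function(x, prefix = "") {
  out <- list()
  if (inherits(x, "ag_node")) {
    if (x$requires_grad) out[[prefix]] <- x
    return(out)
  }
  if (is.list(x)) {
    nm <- names(x)
    for (i in seq_along(x)) {
      tag <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
      out <- c(out, collect_params(x[[i]], paste0(prefix, if (nzchar(prefix)) "." else "", tag)))
    }
  }
  out
}

#' Global average pooling of a (b, c, h, w) node
#' @param x node/array `(b, c, h, w)`.
#' @return `ag_node` of shape `(b, c)`.
#' @export
ag_global_avgpool <- function(x) {
  x <- as_ag(x)
  d <- dim(x$value)
  hw <- d[3L] * d[4L]
  v <- x$value
  dim(v) <- c(d[1L] * d[2L], hw)
  out <- matrix(rowMeans(v), d[1L], d[2L])
  ag_node(out, list(x),
          function(g) list(array(g, d) / hw),   # (b,c) recycles over space
          x$requires_grad)
}

#' Binary cross-entropy with logits (weighted mean over entries)
#'
#' With `weights` given, the loss is `sum(w * bce) / sum(w)` — used by the
#' detector to down-weight background entries (DETR convention).
#'
#' @param logits node/matrix.
#' @param targets numeric matrix in `[0, 1]` (soft targets allowed).
#' @param weights optional nonnegative weight matrix shaped like `targets`.
#' @return scalar `ag_node`.
#' @export
ag_bce_logits <- function(logits, targets, weights = NULL) {
  logits <- as_ag(logits)
  z <- logits$value
  bce <- pmax(z, 0) - z * targets + log1p(exp(-abs(z)))
  if (is.null(weights)) {
    wmat <- 1
    wsum <- length(z)
  } else {
    wmat <- weights
    wsum <- sum(weights)
  }
  val <- sum(wmat * bce) / wsum
  p <- 1 / (1 + exp(-z))
  ag_node(val, list(logits),
          function(g) list(g * wmat * (p - targets) / wsum),
          logits$requires_grad)
}

#' Softmax cross-entropy (mean over rows)
#' @param logits node/matrix `(n, k)`.
#' @param classes integer class ids in `1..k`.
#' @return scalar `ag_node`.
#' @export
ag_softmax_ce <- function(logits, classes) {
  logits <- as_ag(logits)
  z <- logits$value
  n <- nrow(z)
  m <- apply(z, 1L, max)
  lse <- m + log(rowSums(exp(z - m)))
  val <- mean(lse - z[cbind(seq_len(n), classes)])
  p <- exp(z - lse)
  onehot <- matrix(0, n, ncol(z))
  onehot[cbind(seq_len(n), classes)] <- 1
  ag_node(val, list(logits),
          function(g) list(g * (p - onehot) / n),
          logits$requires_grad)
}

#' Fused multi-head scaled-dot-product attention
#'
#' Single tape node computing every head of
#' `softmax(q_m k_m' / sqrt(d_h) + B_m + mask) v_m` and concatenating the
#' results; the hand-derived backward avoids materializing per-head
#' sub-graphs. Inputs are already projected.
#'
#' @param q node/matrix `(n_q, dim)`.
#' @param k,v nodes/matrices `(n_k, dim)`.
#' @param heads head count dividing `dim`.
#' @param mask optional numeric matrix `(n_q, n_k)` added to every head's
#'   scores (use large negatives to block).
#' @param biases optional list (length `heads`) of `(n_q, n_k)` bias nodes.
#' @return `ag_node` of shape `(n_q, dim)`.
#' @export
ag_mha_fused <- function(q, k, v, heads, mask = NULL, biases = NULL) {
  q <- as_ag(q); k <- as_ag(k); v <- as_ag(v)
  qv <- q$value; kv <- k$value; vv <- v$value
  dim_ <- ncol(qv)
  dh <- dim_ %/% heads
  if (dh * heads != dim_) stop("dim must be divisible by heads")
  scl <- 1 / sqrt(dh)
  As <- vector("list", heads)
  out <- matrix(0, nrow(qv), dim_)
  bias_nodes <- if (is.null(biases)) list() else lapply(biases, as_ag)
  for (m in seq_len(heads)) {
    idx <- ((m - 1L) * dh + 1L):(m * dh)
    S <- tcrossprod(qv[, idx, drop = FALSE], kv[, idx, drop = FALSE]) * scl
    if (length(bias_nodes)) S <- S + bias_nodes[[m]]$value
    if (!is.null(mask)) S <- S + mask
    mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
    E <- exp(S - mx)
    A <- E / rowSums(E)
    As[[m]] <- A
    out[, idx] <- A %*% vv[, idx, drop = FALSE]
  }
  parents <- c(list(q, k, v), bias_nodes)
  req <- q$requires_grad || k$requires_grad || v$requires_grad ||
    any(vapply(bias_nodes, function(b) b$requires_grad, TRUE))
  backward <- function(g) {
    gq <- matrix(0, nrow(qv), dim_)
    gk <- matrix(0, nrow(kv), dim_)
    gv <- matrix(0, nrow(vv), dim_)
    gbias <- vector("list", length(bias_nodes))
    for (m in seq_len(heads)) {
      idx <- ((m - 1L) * dh + 1L):(m * dh)
      A <- As[[m]]
      gz <- g[, idx, drop = FALSE]
      dA <- tcrossprod(gz, vv[, idx, drop = FALSE])
      dS <- (dA - rowSums(dA * A)) * A
      gq[, idx] <- dS %*% kv[, idx, drop = FALSE] * scl
      gk[, idx] <- crossprod(dS, qv[, idx, drop = FALSE]) * scl
      gv[, idx] <- crossprod(A, gz)
      if (length(bias_nodes)) gbias[[m]] <- dS
    }
    c(list(gq, gk, gv), gbias)
  }
  ag_node(out, parents, backward, req)
}


#' Scale each row of a matrix node by a per-row weight
#' @param x node/matrix `(n, d)`.
#' @param w node/vector of length `n` (or `(n, 1)` matrix).
#' @return `ag_node` shaped like `x`.
#' @export
ag_row_scale <- function(x, w) {
  x <- as_ag(x); w <- as_ag(w)
  wv <- as.numeric(w$value)
  out <- x$value * wv
  backward <- function(g) {
    gw <- rowSums(g * x$value)
    if (!is.null(dim(w$value))) dim(gw) <- dim(w$value)
    list(g * wv, gw)
  }
  ag_node(out, list(x, w), backward, x$requires_grad || w$requires_grad)
}
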