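# Reverse-mode automatic differentiation tape.
#
# Minimal dynamic-graph engine used by the trainable modules (backbone,
# encoder, decoder, losses). Nodes are environments holding a value, an
# accumulated gradient and a backward closure; the graph is built eagerly by
# the ag_* operations and differentiated by ag_backward(). Values are plain
# R numeric arrays; matrix work goes through BLAS.

.ag_state <- new.env(parent = emptyenv())
.ag_state$counter <- 0L
.ag_state$epoch <- 0L

new_ag_id <- function() {
  .ag_state$counter <- .ag_state$counter + 1L
  .ag_state$counter
}

#' Create a tape node
#'
#' Wraps a numeric array as a node on the differentiation tape. Most users
#' never call this directly; modules create parameters with [ag_param()] and
#' constants are wrapped on the fly.
#'
#' @param value numeric vector, matrix or array.
#' @param parents list of parent nodes the value was computed from.
#' @param backward function mapping the output gradient to a list of parent
#'   gradients (aligned with `parents`; `NULL` entries for constants).
#' @param requires_grad does this node (or an ancestor) need a gradient?
#' @return an object of class `ag_node`.
#' @keywords internal
ag_node <- function(value, parents = list(), backward = NULL,
                    requires_grad = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  e$requires_grad <- requires_grad
  e$id <- new_ag_id()
  class(e) <- "ag_node"
  e
}

#' Trainable parameter node
#' @param value initial numeric value.
#' @return an `ag_node` with `requires_grad = TRUE`.
#' @export
ag_param <- function(value) ag_node(value, requires_grad = TRUE)

#' Constant node
#' @param value numeric value that never receives a gradient.
#' @return an `ag_node` with `requires_grad = FALSE`.
#' @export
ag_const <- function(value) ag_node(value)

as_ag <- function(x) if (inherits(x, "ag_node")) x else ag_const(x)

#' Extract the numeric value of a node
#' @param x an `ag_node` (plain numerics pass through).
#' @return the underlying numeric array.
#' @export
ag_value <- function(x) if (inherits(x, "ag_node")) x$value else x

#' Extract the accumulated gradient of a node
#' @param x an `ag_node`.
#' @return gradient array, or `NULL` if backward has not reached it.
#' @export
ag_grad <- function(x) x$grad

#' @export
print.ag_node <- function(x, ...) {
  d <- dim(x$value)
  cat("<ag_node ", if (is.null(d)) paste0("len ", length(x$value))
      else paste(d, collapse = "x"),
      if (x$requires_grad) " grad" else "", ">\n", sep = "")
  invisible(x)
}

zeros_like <- function(v) {
  if (is.null(dim(v))) numeric(length(v)) else array(0, dim(v))
}

# Post-order topological sort over the requires_grad sub-graph (iterative,
# so deep compositions never hit the C stack).
ag_topo <- function(root) {
  .ag_state$epoch <- .ag_state$epoch + 1L
  ep <- .ag_state$epoch
  order <- vector("list", 256L)
  n <- 0L
  stack <- vector("list", 256L)
  sp <- 1L
  stack[[1L]] <- root
  while (sp > 0L) {
    node <- stack[[sp]]
    if (!isTRUE(node$.ep == ep)) {
      # first encounter: expand (duplicate stack entries are intentional —
      # a node is emitted only after every path into it has been walked)
      node$.ep <- ep
      node$.st <- 1L
      for (p in node$parents) {
        if (inherits(p, "ag_node") && p$requires_grad &&
            !isTRUE(p$.ep == ep)) {
          sp <- sp + 1L
          if (sp > length(stack)) stack <- c(stack, vector("list", length(stack)))
          stack[[sp]] <- p
        }
      }
    } else if (node$.st == 1L) {
      node$.st <- 2L
      sp <- sp - 1L
      n <- n + 1L
      if (n > length(order)) order <- c(order, vector("list", length(order)))
      order[[n]] <- node
    } else {
      sp <- sp - 1L
    }
  }
  order[seq_len(n)]
}

#' Backpropagate gradients from a node
#'
#' Accumulates gradients into every `requires_grad` ancestor of `root`.
#' Gradients add up across calls; clear them with [ag_zero_grad()].
#'
#' @param root node to differentiate (typically a scalar loss).
#' @param grad seed gradient; defaults to 1 for scalars / all-ones otherwise.
#' @return invisibly, `root`.
#' @export
ag_backward <- function(root, grad = NULL) {
  if (!root$requires_grad) return(invisible(root))
  if (is.null(grad)) {
    grad <- zeros_like(root$value)
    grad[] <- 1
  }
  order <- ag_topo(root)
  root$.g <- grad
  for (i in rev(seq_along(order))) {
    node <- order[[i]]
    g <- node$.g
    if (is.null(g)) next
    if (is.null(node$backward)) {
      node$grad <- if (is.null(node$grad)) g else node$grad + g
      node$.g <- NULL
      next
    }
    pgrads <- node$backward(g)
    ps <- node$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (!inherits(p, "ag_node") || !p$requires_grad) next
      pg <- pgrads[[j]]
      if (is.null(pg)) next
      p$.g <- if (is.null(p$.g)) pg else p$.g + pg
    }
    if (isTRUE(node$retain_grad)) {
      node$grad <- if (is.null(node$grad)) g else node$grad + g
    }
    node$.g <- NULL
  }
  invisible(root)
}

#' Reset accumulated gradients
#' @param params list of `ag_node` parameters.
#' @return invisibly `NULL`.
#' @export
ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- elementwise arithmetic ------------------------------------------------

same_or_scalar <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la != lb && la != 1L && lb != 1L)
    stop("shape mismatch in elementwise op: ", la, " vs ", lb)
}

reduce_to <- function(g, template) {
  if (length(template) == 1L && length(g) > 1L) sum(g) else g
}

#' Elementwise tape operations
#'
#' `ag_add`, `ag_sub`, `ag_mul` operate elementwise (either operand may be a
#' scalar); `ag_scale` multiplies by a fixed numeric; `ag_neg` negates.
#'
#' @param a,b nodes or numerics.
#' @param k fixed numeric scalar.
#' @param x node or numeric.
#' @return an `ag_node`.
#' @name ag-elementwise
NULL

#' @rdname ag-elementwise
#' @export
ag_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  same_or_scalar(a$value, b$value)
  av <- a$value; bv <- b$value
  ag_node(av + bv, list(a, b),
          function(g) list(reduce_to(g, av), reduce_to(g, bv)),
          a$requires_grad || b$requires_grad)
}

#' @rdname ag-elementwise
#' @export
ag_sub <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  same_or_scalar(a$value, b$value)
  av <- a$value; bv <- b$value
  ag_node(av - bv, list(a, b),
          function(g) list(reduce_to(g, av), reduce_to(-g, bv)),
          a$requires_grad || b$requires_grad)
}

#' @rdname ag-elementwise
#' @export
ag_mul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  same_or_scalar(a$value, b$value)
  av <- a$value; bv <- b$value
  ag_node(av * bv, list(a, b),
          function(g) list(reduce_to(g * bv, av), reduce_to(g * av, bv)),
          a$requires_grad || b$requires_grad)
}

#' @rdname ag-elementwise
#' @export
ag_scale <- function(x, k) {
  x <- as_ag(x)
  ag_node(x$value * k, list(x), function(g) list(g * k), x$requires_grad)
}

#' @rdname ag-elementwise
#' @export
ag_neg <- function(x) ag_scale(x, -1)

#' Elementwise nonlinearities and clamps
#'
#' ReLU, sigmoid, tanh, absolute value (subgradient 0 at 0), elementwise
#' min/max of two arrays (subgradient follows the selected operand, first
#' operand on ties), and square root.
#'
#' @param x,a,b nodes or numerics.
#' @return an `ag_node`.
#' @name ag-nonlinear
NULL

#' @rdname ag-nonlinear
#' @export
ag_relu <- function(x) {
  x <- as_ag(x)
  mask <- x$value > 0
  ag_node(x$value * mask, list(x), function(g) list(g * mask), x$requires_grad)
}

#' @rdname ag-nonlinear
#' @export
ag_sigmoid <- function(x) {
  x <- as_ag(x)
  y <- 1 / (1 + exp(-x$value))
  ag_node(y, list(x), function(g) list(g * y * (1 - y)), x$requires_grad)
}

#' @rdname ag-nonlinear
#' @export
ag_tanh <- function(x) {
  x <- as_ag(x)
  y <- tanh(x$value)
  ag_node(y, list(x), function(g) list(g * (1 - y * y)), x$requires_grad)
}

#' @rdname ag-nonlinear
#' @export
ag_abs <- function(x) {
  x <- as_ag(x)
  s <- sign(x$value)
  ag_node(abs(x$value), list(x), function(g) list(g * s), x$requires_grad)
}

#' @rdname ag-nonlinear
#' @export
ag_pmin <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  same_or_scalar(a$value, b$value)
  take_a <- a$value <= b$value
  ag_node(pmin(a$value, b$value), list(a, b),
          function(g) list(reduce_to(g * take_a, a$value),
                           reduce_to(g * !take_a, b$value)),
          a$requires_grad || b$requires_grad)
}

#' @rdname ag-nonlinear
#' @export
ag_pmax <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  same_or_scalar(a$value, b$value)
  take_a <- a$value >= b$value
  ag_node(pmax(a$value, b$value), list(a, b),
          function(g) list(reduce_to(g * take_a, a$value),
                           reduce_to(g * !take_a, b$value)),
          a$requires_grad || b$requires_grad)
}

#' @rdname ag-nonlinear
#' @export
ag_sqrt <- function(x) {
  x <- as_ag(x)
  y <- sqrt(x$value)
  ag_node(y, list(x), function(g) list(g * 0.5 / pmax(y, 1e-12)),
          x$requires_grad)
}

#' @rdname ag-nonlinear
#' @export
ag_log <- function(x) {
  x <- as_ag(x)
  v <- x$value
  ag_node(log(v), list(x), function(g) list(g / v), x$requires_grad)
}

# ---- linear algebra --------------------------------------------------------

#' Matrix product of two tape nodes
#' @param a node/matrix `(n, k)`.
#' @param b node/matrix `(k, m)`.
#' @return `ag_node` holding the `(n, m)` product.
#' @export
ag_matmul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  av <- a$value; bv <- b$value
  ag_node(av %*% bv, list(a, b),
          function(g) list(g %*% t(bv), crossprod(av, g)),
          a$requires_grad || b$requires_grad)
}

#' Affine layer: `x %*% W + b` with the bias broadcast over rows
#' @param x node/matrix `(n, d_in)`.
#' @param W node/matrix `(d_in, d_out)`.
#' @param b node/vector length `d_out`, or `NULL`.
#' @return `ag_node` of shape `(n, d_out)`.
#' @export
ag_linear <- function(x, W, b = NULL) {
  x <- as_ag(x); W <- as_ag(W)
  y <- x$value %*% W$value
  if (is.null(b)) {
    return(ag_node(y, list(x, W),
                   function(g) list(g %*% t(W$value), crossprod(x$value, g)),
                   x$requires_grad || W$requires_grad))
  }
  b <- as_ag(b)
  yv <- sweep(y, 2L, b$value, "+")
  ag_node(yv, list(x, W, b),
          function(g) list(g %*% t(W$value), crossprod(x$value, g),
                           colSums(g)),
          x$requires_grad || W$requires_grad || b$requires_grad)
}

#' Row-wise softmax of a matrix node
#' @param x node/matrix; softmax is taken along each row.
#' @return `ag_node` with rows summing to 1.
#' @export
ag_softmax <- function(x) {
  x <- as_ag(x)
  v <- x$value
  m <- v[cbind(seq_len(nrow(v)), max.col(v, ties.method = "first"))]
  e <- exp(v - m)
  y <- e / rowSums(e)
  ag_node(y, list(x),
          function(g) list((g - rowSums(g * y)) * y),
          x$requires_grad)
}

# ---- reductions & shape ----------------------------------------------------

#' Reductions and shape manipulation on the tape
#'
#' `ag_sum`/`ag_mean` reduce to a scalar; `ag_reshape` changes `dim`
#' losslessly; `ag_aperm` generalizes transpose; `ag_rowsums`/`ag_colsums`
#' reduce matrices along one margin.
#'
#' @param x a node.
#' @param d target `dim` for `ag_reshape`.
#' @param perm permutation for `ag_aperm`.
#' @return an `ag_node`.
#' @name ag-shape
NULL

#' @rdname ag-shape
#' @export
ag_sum <- function(x) {
  x <- as_ag(x)
  v <- x$value
  ag_node(sum(v), list(x),
          function(g) list({ gg <- zeros_like(v); gg[] <- g; gg }),
          x$requires_grad)
}

#' @rdname ag-shape
#' @export
ag_mean <- function(x) {
  x <- as_ag(x)
  n <- length(x$value)
  ag_scale(ag_sum(x), 1 / n)
}

#' @rdname ag-shape
#' @export
ag_reshape <- function(x, d) {
  x <- as_ag(x)
  old <- dim(x$value)
  v <- x$value
  dim(v) <- d
  ag_node(v, list(x),
          function(g) list({ dim(g) <- if (is.null(old)) NULL else old; g }),
          x$requires_grad)
}

#' @rdname ag-shape
#' @export
ag_aperm <- function(x, perm) {
  x <- as_ag(x)
  inv <- order(perm)
  ag_node(aperm(x$value, perm), list(x),
          function(g) list(aperm(g, inv)), x$requires_grad)
}

#' @rdname ag-shape
#' @export
ag_rowsums <- function(x) {
  x <- as_ag(x)
  v <- x$value
  ag_node(rowSums(v), list(x),
          function(g) list(matrix(g, nrow(v), ncol(v))),
          x$requires_grad)
}

#' @rdname ag-shape
#' @export
ag_colsums <- function(x) {
  x <- as_ag(x)
  v <- x$value
  ag_node(colSums(v), list(x),
          function(g) list(matrix(g, nrow(v), ncol(v), byrow = TRUE)),
          x$requires_grad)
}

# ---- gather / concatenate --------------------------------------------------

#' Row gather with scatter-add backward
#' @param x node/matrix.
#' @param idx integer row indices (may repeat).
#' @return `ag_node` with `length(idx)` rows.
#' @export
ag_rows <- function(x, idx) {
  x <- as_ag(x)
  v <- x$value
  ag_node(v[idx, , drop = FALSE], list(x),
          function(g) {
            gx <- matrix(0, nrow(v), ncol(v))
            # scatter-add: idx may contain duplicates
            agg <- rowsum(g, group = idx)
            gx[as.integer(rownames(agg)), ] <- agg
            list(gx)
          },
          x$requires_grad)
}

#' Column gather
#' @param x node/matrix.
#' @param idx integer column indices (no duplicates expected).
#' @return `ag_node` with `length(idx)` columns.
#' @export
ag_cols <- function(x, idx) {
  x <- as_ag(x)
  v <- x$value
  ag_node(v[, idx, drop = FALSE], list(x),
          function(g) {
            gx <- matrix(0, nrow(v), ncol(v))
            gx[, idx] <- gx[, idx] + g
            list(gx)
          },
          x$requires_grad)
}

#' Concatenate matrix nodes by rows or columns
#' @param xs list of nodes with compatible shapes.
#' @return an `ag_node`.
#' @name ag-concat
NULL

#' @rdname ag-concat
#' @export
ag_rbind <- function(xs) {
  xs <- lapply(xs, as_ag)
  ns <- vapply(xs, function(x) nrow(x$value), 1L)
  v <- do.call(rbind, lapply(xs, ag_value))
  ends <- cumsum(ns)
  starts <- ends - ns + 1L
  ag_node(v, xs,
          function(g) lapply(seq_along(xs), function(i)
            g[starts[i]:ends[i], , drop = FALSE]),
          any(vapply(xs, function(x) x$requires_grad, TRUE)))
}

#' @rdname ag-concat
#' @export
ag_cbind <- function(xs) {
  xs <- lapply(xs, as_ag)
  ns <- vapply(xs, function(x) ncol(x$value), 1L)
  v <- do.call(cbind, lapply(xs, ag_value))
  ends <- cumsum(ns)
  starts <- ends - ns + 1L
  ag_node(v, xs,
          function(g) lapply(seq_along(xs), function(i)
            g[, starts[i]:ends[i], drop = FALSE]),
          any(vapply(xs, function(x) x$requires_grad, TRUE)))
}

# ---- optimizer -------------------------------------------------------------

#' Adam optimizer over a flat list of parameters
#'
#' @param params named list of `ag_node` parameters.
#' @param lr learning rate.
#' @param beta1,beta2 moment decay rates.
#' @param eps numerical floor in the update denominator.
#' @return an optimizer object; call [adam_step()] after each backward pass.
#' @export
adam <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$params <- params
  opt$lr <- lr; opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$t <- 0L
  opt$m <- lapply(params, function(p) zeros_like(p$value))
  opt$v <- lapply(params, function(p) zeros_like(p$value))
  class(opt) <- "ag_adam"
  opt
}

#' Apply one Adam update (in place) and clear gradients
#' @param opt optimizer from [adam()].
#' @param clip optional global-norm gradient clip.
#' @return invisibly, the optimizer.
#' @export
adam_step <- function(opt, clip = NULL) {
  opt$t <- opt$t + 1L
  scale <- 1
  if (!is.null(clip)) {
    tot <- 0
    for (p in opt$params) if (!is.null(p$grad)) tot <- tot + sum(p$grad^2)
    nrm <- sqrt(tot)
    if (nrm > clip) scale <- clip / (nrm + 1e-12)
  }
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    if (is.null(p$grad)) next
    g <- p$grad * scale
    opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
    opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * g * g
    p$value <- p$value - opt$lr * (opt$m[[i]] / bc1) /
      (sqrt(opt$v[[i]] / bc2) + opt$eps)
    p$grad <- NULL
  }
  invisible(opt)
}
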