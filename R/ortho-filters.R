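# Frozen orthogonal channel-attention filters.
#
# Each channel of a square feature map gets its own n x n filter drawn from
# the special orthogonal group SO(n) = { R : R'R = I, det(R) = +1 }. Two
# bank flavours exist: "special_orthogonal" (orthogonality *within* every
# filter, the package's default) and "gram_schmidt" (OrthoNets-style
# orthogonality *between* flattened filters), kept for the ablation.

#' Sample a Haar-distributed element of SO(n)
#'
#' Draws an i.i.d. standard-normal matrix, takes its QR decomposition with
#' the R-factor diagonal sign-corrected (the standard construction of Haar
#' measure on O(n)), and negates one column if the determinant is -1 so the
#' result lands in SO(n). Deterministic for a fixed `(n, seed)` pair.
#'
#' @param n matrix side (filter spatial size), positive integer.
#' @param seed integer seed.
#' @return an `ortho_matrix`: the `n x n` matrix with attributes `n`, `seed`.
#' @examples
#' R <- sample_special_orthogonal(4, seed = 7)
#' max(abs(crossprod(R) - diag(4)))   # ~ 1e-16
#' det(R)                             # +1
#' @export
sample_special_orthogonal <- function(n, seed = 0L) {
  if (length(n) != 1L || is.na(n) || n < 1 || n != round(n))
    stop("`n` must be a positive integer")
  n <- as.integer(n)
  R <- with_seed(seed, {
    if (n == 1L) matrix(1, 1, 1) else {
      A <- matrix(stats::rnorm(n * n), n, n)
      qr_ <- qr(A)
      Q <- qr.Q(qr_)
      d <- sign(diag(qr.R(qr_)))
      d[d == 0] <- 1
      Q <- sweep(Q, 2L, d, "*")
      if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
      Q
    }
  })
  structure(R, n = n, seed = as.integer(seed), class = c("ortho_matrix", "matrix"))
}

#' Validate membership in SO(n)
#' @param R square numeric matrix.
#' @param tol tolerance on both the Gram residual and the determinant.
#' @return `TRUE` if `max|R'R - I| <= tol` and `|det(R) - 1| <= tol`.
#' @export
is_special_orthogonal <- function(R, tol = 1e-5) {
  R <- unclass(R)
  n <- nrow(R)
  max(abs(crossprod(R) - diag(n))) <= tol && abs(det(R) - 1) <= tol
}

#' Build a frozen filter bank
#'
#' `special_orthogonal` mode samples `c` independent SO(n) matrices (seeds
#' `seed + 0:(c-1)`, one per channel); `gram_schmidt` mode draws `c` random
#' filters, flattens them to length-`n^2` vectors and orthonormalizes them
#' against each other, so the *between*-filter Gram matrix is the identity
#' (requires `c <= n^2`).
#'
#' @param c channel count (number of filters).
#' @param n filter side.
#' @param mode `"special_orthogonal"` or `"gram_schmidt"`.
#' @param seed integer seed.
#' @return a `filter_bank`: list with `c`, `n`, `mode`, `seed`, and
#'   `matrices` (array `(c, n, n)`).
#' @examples
#' fb <- build_filter_bank(3, 2, "special_orthogonal", seed = 1)
#' sapply(1:3, function(i) det(fb$matrices[i, , ]))
#' @export
build_filter_bank <- function(c, n,
                              mode = c("special_orthogonal", "gram_schmidt"),
                              seed = 0L) {
  mode <- match.arg(mode)
  if (c < 1 || c != round(c)) stop("`c` must be a positive integer")
  if (n < 1 || n != round(n)) stop("`n` must be a positive integer")
  c <- as.integer(c); n <- as.integer(n)
  mats <- array(0, c(c, n, n))
  if (mode == "special_orthogonal") {
    for (i in seq_len(c))
      mats[i, , ] <- sample_special_orthogonal(n, seed + i - 1L)
  } else {
    if (c > n * n)
      stop("gram_schmidt mode needs c <= n^2 (cannot fit ", c,
           " orthonormal vectors in dimension ", n * n, ")")
    V <- with_seed(seed, matrix(stats::rnorm(n * n * c), n * n, c))
    # modified Gram-Schmidt on the flattened filters
    for (j in seq_len(c)) {
      v <- V[, j]
      if (j > 1L) {
        Q <- V[, seq_len(j - 1L), drop = FALSE]
        v <- v - Q %*% crossprod(Q, v)
        v <- v - Q %*% crossprod(Q, v)   # re-orthogonalize for stability
      }
      nv <- sqrt(sum(v^2))
      if (nv < 1e-10) stop("degenerate draw in gram_schmidt orthonormalization")
      V[, j] <- v / nv
    }
    for (i in seq_len(c)) mats[i, , ] <- matrix(V[, i], n, n)
  }
  structure(list(c = c, n = n, mode = mode, seed = as.integer(seed),
                 matrices = mats),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat("<filter_bank c=", x$c, " n=", x$n, " mode=", x$mode,
      " seed=", x$seed, ">\n", sep = "")
  invisible(x)
}

#' Empirical Lipschitz ratio of an orthogonal + ReLU chain
#'
#' Evaluates `f(x) = W_L relu( ... relu(W_1 x))` at two inputs and returns
#' `||f(x) - f(y)|| / ||x - y||`. When every `W_l` is orthogonal the spectral
#' norms are all 1 and the ratio can never exceed 1 (ReLU is 1-Lipschitz);
#' this is the network-level contraction property that motivates
#' orthogonally initialized filters.
#'
#' @param weight_mats list of weight matrices, applied first-to-last; layer
#'   `l+1` input dim must equal layer `l` output dim.
#' @param x,y input vectors (distinct).
#' @return the ratio, a nonnegative scalar.
#' @export
verify_lipschitz_chain <- function(weight_mats, x, y) {
  if (isTRUE(all.equal(as.numeric(x), as.numeric(y), tolerance = 0)) ||
      sum((x - y)^2) == 0)
    stop("x and y must differ: ratio undefined at x == y")
  run <- function(v) {
    L <- length(weight_mats)
    for (l in seq_len(L)) {
      v <- as.numeric(weight_mats[[l]] %*% v)
      if (l < L) v <- pmax(v, 0)
    }
    v
  }
  fx <- run(as.numeric(x))
  fy <- run(as.numeric(y))
  sqrt(sum((fx - fy)^2)) / sqrt(sum((as.numeric(x) - as.numeric(y))^2))
}

#' Serialize / restore a filter bank
#'
#' Writes the stacked filters as a flat little-endian double array plus a
#' JSON sidecar (`c`, `n`, `mode`, `seed`) so a bank can be restored
#' bit-exactly.
#'
#' @param bank a `filter_bank`.
#' @param path file path for the binary array; the sidecar is `path` +
#'   `".json"`.
#' @return invisibly, `path` (for `save_filter_bank`); the restored
#'   `filter_bank` (for `load_filter_bank`).
#' @name filter-bank-io
NULL

#' @rdname filter-bank-io
#' @export
save_filter_bank <- function(bank, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(bank$matrices), con, size = 8L, endian = "little")
  jsonlite::write_json(list(c = bank$c, n = bank$n, mode = bank$mode,
                            seed = bank$seed),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname filter-bank-io
#' @export
load_filter_bank <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = meta$c * meta$n^2, size = 8L,
                  endian = "little")
  structure(list(c = as.integer(meta$c), n = as.integer(meta$n),
                 mode = meta$mode, seed = as.integer(meta$seed),
                 matrices = array(vals, c(meta$c, meta$n, meta$n))),
            class = "filter_bank")
}
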