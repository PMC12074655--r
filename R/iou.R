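# Box geometry: center-size <-> corner conversion, Inner-IoU on
# center-scaled boxes, normalized corner-distance penalties, and the
# combined IACD-IoU score and loss. All numeric functions are vectorized
# over data-frame rows; a tape version of the loss drives training.
#
# Conventions: boxes live in continuous real coordinates (no pixel
# discretization); center-size boxes have columns cx, cy, w, h; corner
# boxes have bl (left), bt (top), br (right), bb (bottom).

eps_union <- 1e-9

as_box_df <- function(b) {
  b <- as.data.frame(b)
  stopifnot(all(c("cx", "cy", "w", "h") %in% names(b)))
  b
}

#' Convert center-size boxes to corners, optionally scaling about centers
#'
#' Corners are `center +/- side * ratio / 2`; `ratio = 1` is the plain
#' conversion, `ratio < 1` shrinks each box about its own center (the
#' construction Inner-IoU evaluates overlap on).
#'
#' @param box data frame with columns `cx, cy, w, h`.
#' @param ratio positive scale factor (the interior-emphasis ratio; 0.7 in
#'   the detector's loss).
#' @return data frame with columns `bl, bt, br, bb`.
#' @examples
#' scale_box(data.frame(cx = 50, cy = 50, w = 20, h = 20), ratio = 0.7)
#' # corners (43, 43, 57, 57)
#' @export
scale_box <- function(box, ratio = 1) {
  if (ratio <= 0) stop("ratio must be positive")
  box <- as_box_df(box)
  data.frame(bl = box$cx - box$w * ratio / 2,
             bt = box$cy - box$h * ratio / 2,
             br = box$cx + box$w * ratio / 2,
             bb = box$cy + box$h * ratio / 2)
}

#' Plain IoU of corner boxes (closed form)
#' @param a,b data frames with `bl, bt, br, bb` (row-aligned).
#' @return numeric vector in `[0, 1]`.
#' @export
iou_corners <- function(a, b) {
  iw <- pmax(0, pmin(a$br, b$br) - pmax(a$bl, b$bl))
  ih <- pmax(0, pmin(a$bb, b$bb) - pmax(a$bt, b$bt))
  inter <- iw * ih
  ua <- pmax(0, a$br - a$bl) * pmax(0, a$bb - a$bt)
  ub <- pmax(0, b$br - b$bl) * pmax(0, b$bb - b$bt)
  inter / pmax(ua + ub - inter, eps_union)
}

#' Plain IoU of center-size boxes
#' @param a,b data frames with `cx, cy, w, h` (row-aligned).
#' @return numeric vector in `[0, 1]`.
#' @export
iou_cxcywh <- function(a, b) iou_corners(scale_box(a, 1), scale_box(b, 1))

#' Generalized IoU (comparison baseline)
#' @param a,b data frames with `cx, cy, w, h` (row-aligned).
#' @return numeric vector in `(-1, 1]`.
#' @export
giou_cxcywh <- function(a, b) {
  ca <- scale_box(a, 1); cb <- scale_box(b, 1)
  iou <- iou_corners(ca, cb)
  cw <- pmax(ca$br, cb$br) - pmin(ca$bl, cb$bl)
  ch <- pmax(ca$bb, cb$bb) - pmin(ca$bt, cb$bt)
  hull <- pmax(cw * ch, eps_union)
  ua <- (ca$br - ca$bl) * (ca$bb - ca$bt)
  ub <- (cb$br - cb$bl) * (cb$bb - cb$bt)
  iw <- pmax(0, pmin(ca$br, cb$br) - pmax(ca$bl, cb$bl))
  ih <- pmax(0, pmin(ca$bb, cb$bb) - pmax(ca$bt, cb$bt))
  union <- ua + ub - iw * ih
  iou - (hull - union) / hull
}

#' Interior-focused IoU (Inner-IoU)
#'
#' Both boxes are shrunk about their centers by `ratio` and the IoU is
#' taken on the shrunk boxes, so overlap deep inside the boxes counts for
#' more than overlap near their rims. Each axis overlap is clamped at zero
#' before multiplying (disjoint shrunk boxes give exactly 0), and the
#' union carries a small epsilon guard against degenerate boxes.
#'
#' @param gt,anchor data frames with `cx, cy, w, h` (row-aligned).
#' @param ratio positive interior-emphasis ratio (default 0.7).
#' @return numeric vector in `[0, 1]`.
#' @examples
#' inner_iou(data.frame(cx = 50, cy = 50, w = 20, h = 20),
#'           data.frame(cx = 55, cy = 55, w = 20, h = 20), ratio = 0.7)
#' # 81/311
#' @export
inner_iou <- function(gt, anchor, ratio = 0.7) {
  if (ratio <= 0) stop("ratio must be positive")
  gt <- as_box_df(gt); anchor <- as_box_df(anchor)
  g <- scale_box(gt, ratio)
  a <- scale_box(anchor, ratio)
  iw <- pmax(0, pmin(g$br, a$br) - pmax(g$bl, a$bl))
  ih <- pmax(0, pmin(g$bb, a$bb) - pmax(g$bt, a$bt))
  inter <- iw * ih
  union <- ratio * gt$w * ratio * gt$h + ratio * anchor$w * ratio * anchor$h -
    inter
  inter / pmax(union, eps_union)
}

#' Normalized squared corner distances
#'
#' `p1 = d1^2 / (w^2 + h^2)` for the top-left corners and `p2` likewise for
#' the bottom-right corners, with `(w, h)` the image extent — the MPDIoU
#' penalty pair.
#'
#' @param gt_c,anchor_c data frames with `bl, bt, br, bb` (row-aligned).
#' @param img_w,img_h image extent in the same units as the corners.
#' @return data frame with columns `p1`, `p2`.
#' @export
corner_penalty <- function(gt_c, anchor_c, img_w, img_h) {
  if (img_w <= 0 || img_h <= 0) stop("image extent must be positive")
  den <- img_w^2 + img_h^2
  d1 <- (anchor_c$bl - gt_c$bl)^2 + (anchor_c$bt - gt_c$bt)^2
  d2 <- (anchor_c$br - gt_c$br)^2 + (anchor_c$bb - gt_c$bb)^2
  data.frame(p1 = d1 / den, p2 = d2 / den)
}

#' Interior-aware corner-distance IoU (IACD-IoU)
#'
#' `IoU_inner - p1 - p2`: the interior-focused IoU of the center-scaled
#' boxes minus the two normalized corner-distance penalties. With
#' `corner_mode = "scaled"` (default) the penalties are measured on the
#' scaled corners — the literal composition of the defining equations; for
#' equal-size boxes the two modes coincide because scaling about centers
#' preserves corner differences up to the (identical) size term.
#'
#' @param gt,anchor data frames with `cx, cy, w, h` (row-aligned).
#' @param ratio interior-emphasis ratio.
#' @param img_w,img_h image extent.
#' @param corner_mode `"scaled"` or `"original"` corners for the penalty.
#' @return numeric vector; 1 iff the boxes coincide, negative for
#'   well-separated boxes, bounded below by -2 for in-image boxes.
#' @examples
#' iacd_iou(data.frame(cx = 50, cy = 50, w = 20, h = 20),
#'          data.frame(cx = 55, cy = 55, w = 20, h = 20),
#'          ratio = 0.7, img_w = 100, img_h = 100)
#' # 81/311 - 0.005
#' @export
iacd_iou <- function(gt, anchor, ratio = 0.7, img_w, img_h,
                     corner_mode = c("scaled", "original")) {
  corner_mode <- match.arg(corner_mode)
  gt <- as_box_df(gt); anchor <- as_box_df(anchor)
  ii <- inner_iou(gt, anchor, ratio)
  r <- if (corner_mode == "scaled") ratio else 1
  pen <- corner_penalty(scale_box(gt, r), scale_box(anchor, r), img_w, img_h)
  ii - pen$p1 - pen$p2
}

#' IACD-IoU regression loss
#'
#' Mean (or sum) of `1 - IACD-IoU` over row-aligned box pairs; 0 exactly
#' when every pair coincides.
#'
#' @param pred,gt data frames with `cx, cy, w, h` (equal row counts).
#' @param ratio,img_w,img_h,corner_mode passed to [iacd_iou()].
#' @param reduction `"mean"` or `"sum"`.
#' @return nonnegative scalar.
#' @export
iacd_loss <- function(pred, gt, ratio = 0.7, img_w = 1, img_h = 1,
                      corner_mode = "scaled", reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  pred <- as_box_df(pred); gt <- as_box_df(gt)
  if (nrow(pred) != nrow(gt)) stop("pred and gt must have equal row counts")
  v <- 1 - iacd_iou(gt, pred, ratio, img_w, img_h, corner_mode)
  if (reduction == "mean") mean(v) else sum(v)
}

# ---- tape version (drives the detector's box loss) -------------------------

#' IACD-IoU loss on the tape
#'
#' Differentiable version of [iacd_loss()] for `(n, 4)` box nodes in
#' `cx, cy, w, h` column order (normalized coordinates, `img_w = img_h = 1`
#' by default). Ground truth may be a plain matrix. Implemented as a single
#' fused tape node with an analytic (sub)gradient in the predicted boxes.
#'
#' @param pred node/matrix `(n, 4)`.
#' @param gt matrix `(n, 4)`.
#' @param ratio,img_w,img_h,corner_mode as in [iacd_iou()].
#' @return scalar `ag_node` (mean of `1 - IACD-IoU`).
#' @export
ag_iacd_loss <- function(pred, gt, ratio = 0.7, img_w = 1, img_h = 1,
                         corner_mode = "scaled") {
  pred <- as_ag(pred)
  P <- pred$value
  G <- as.matrix(ag_value(gt))
  n <- nrow(P)
  half <- ratio / 2
  r2 <- if (corner_mode == "scaled") half else 0.5
  den <- img_w^2 + img_h^2
  px <- P[, 1]; py <- P[, 2]; pw <- P[, 3]; ph <- P[, 4]
  gx <- G[, 1]; gy <- G[, 2]; gw <- G[, 3]; gh <- G[, 4]
  al <- px - pw * half; ar <- px + pw * half
  at <- py - ph * half; ab <- py + ph * half
  gl <- gx - gw * half; gr <- gx + gw * half
  gtt <- gy - gh * half; gb <- gy + gh * half
  iwr <- pmin(gr, ar) - pmax(gl, al)
  ihr <- pmin(gb, ab) - pmax(gtt, at)
  iw <- pmax(iwr, 0); ih <- pmax(ihr, 0)
  I <- iw * ih
  U0 <- ratio^2 * (gw * gh + pw * ph) - I
  U <- pmax(U0, eps_union)
  ii <- I / U
  e1x <- (px - pw * r2) - (gx - gw * r2)
  e1y <- (py - ph * r2) - (gy - gh * r2)
  e2x <- (px + pw * r2) - (gx + gw * r2)
  e2y <- (py + ph * r2) - (gy + gh * r2)
  pen <- (e1x^2 + e1y^2 + e2x^2 + e2y^2) / den
  val <- mean(1 - ii + pen)
  backward <- function(g) {
    ax <- (iwr > 0) * ih              # d I wrt x-side corner movement
    ay <- (ihr > 0) * iw
    sx1 <- as.numeric(ar <= gr); sx0 <- as.numeric(al >= gl)
    sy1 <- as.numeric(ab <= gb); sy0 <- as.numeric(at >= gtt)
    dI_px <- ax * (sx1 - sx0)
    dI_pw <- ax * half * (sx1 + sx0)
    dI_py <- ay * (sy1 - sy0)
    dI_ph <- ay * half * (sy1 + sy0)
    uact <- as.numeric(U0 > eps_union)
    dU_px <- uact * (-dI_px)
    dU_py <- uact * (-dI_py)
    dU_pw <- uact * (ratio^2 * ph - dI_pw)
    dU_ph <- uact * (ratio^2 * pw - dI_ph)
    dii <- function(dI, dU) (dI * U - I * dU) / U^2
    gmat <- cbind(
      -dii(dI_px, dU_px) + 2 * (e1x + e2x) / den,
      -dii(dI_py, dU_py) + 2 * (e1y + e2y) / den,
      -dii(dI_pw, dU_pw) + 2 * r2 * (e2x - e1x) / den,
      -dii(dI_ph, dU_ph) + 2 * r2 * (e2y - e1y) / den) * (g / n)
    list(gmat)
  }
  ag_node(val, list(pred), backward, pred$requires_grad)
}

# ---- rasterized oracle -----------------------------------------------------

#' Rasterized IoU oracle
#'
#' Independent verification oracle: lays a square lattice of pitch `step`
#' over the plane (cell centers at `(k - 1/2) * step`), counts cells whose
#' center falls inside both boxes and inside either box, and returns the
#' ratio. Because the boxes are axis-aligned the 2-D counts factor into
#' per-axis counts (inclusion-exclusion for "either"), which this function
#' exploits; the result is identical to the literal cell-by-cell scan.
#'
#' @param a,b single-row data frames (or lists) with `bl, bt, br, bb`.
#' @param step lattice pitch (same units as the corners).
#' @return rasterized IoU estimate in `[0, 1]`.
#' @export
rasterized_iou_oracle <- function(a, b, step = 0.01) {
  if (step <= 0) stop("step must be positive")
  nlat <- function(l, r) {
    if (r < l) return(0)
    max(0, floor(r / step + 0.5) - ceiling(l / step + 0.5) + 1)
  }
  nx_a <- nlat(a$bl, a$br); ny_a <- nlat(a$bt, a$bb)
  nx_b <- nlat(b$bl, b$br); ny_b <- nlat(b$bt, b$bb)
  nx_i <- nlat(max(a$bl, b$bl), min(a$br, b$br))
  ny_i <- nlat(max(a$bt, b$bt), min(a$bb, b$bb))
  both <- nx_i * ny_i
  either <- nx_a * ny_a + nx_b * ny_b - both
  if (either == 0) return(0)
  both / either
}


# matrix fast paths (no data-frame overhead) used by the matcher and the
# evaluator; semantics identical to the data-frame functions above

iou_mat <- function(a, b) {
  # a, b: (n, 4) matrices of cx, cy, w, h, row-aligned
  al <- a[, 1] - a[, 3] / 2; ar <- a[, 1] + a[, 3] / 2
  at <- a[, 2] - a[, 4] / 2; ab <- a[, 2] + a[, 4] / 2
  bl <- b[, 1] - b[, 3] / 2; br <- b[, 1] + b[, 3] / 2
  bt <- b[, 2] - b[, 4] / 2; bb <- b[, 2] + b[, 4] / 2
  iw <- pmax(0, pmin(ar, br) - pmax(al, bl))
  ih <- pmax(0, pmin(ab, bb) - pmax(at, bt))
  inter <- iw * ih
  inter / pmax(a[, 3] * a[, 4] + b[, 3] * b[, 4] - inter, eps_union)
}

iacd_iou_mat <- function(gt, anchor, ratio = 0.7, img_w = 1, img_h = 1,
                         corner_mode = "scaled") {
  h2 <- ratio / 2
  gl <- gt[, 1] - gt[, 3] * h2; gr <- gt[, 1] + gt[, 3] * h2
  gt_ <- gt[, 2] - gt[, 4] * h2; gb <- gt[, 2] + gt[, 4] * h2
  al <- anchor[, 1] - anchor[, 3] * h2; ar <- anchor[, 1] + anchor[, 3] * h2
  at <- anchor[, 2] - anchor[, 4] * h2; ab <- anchor[, 2] + anchor[, 4] * h2
  iw <- pmax(0, pmin(gr, ar) - pmax(gl, al))
  ih <- pmax(0, pmin(gb, ab) - pmax(gt_, at))
  inter <- iw * ih
  union <- ratio^2 * (gt[, 3] * gt[, 4] + anchor[, 3] * anchor[, 4]) - inter
  ii <- inter / pmax(union, eps_union)
  r2 <- if (corner_mode == "scaled") h2 else 0.5
  d1 <- ((anchor[, 1] - anchor[, 3] * r2) - (gt[, 1] - gt[, 3] * r2))^2 +
    ((anchor[, 2] - anchor[, 4] * r2) - (gt[, 2] - gt[, 4] * r2))^2
  d2 <- ((anchor[, 1] + anchor[, 3] * r2) - (gt[, 1] + gt[, 3] * r2))^2 +
    ((anchor[, 2] + anchor[, 4] * r2) - (gt[, 2] + gt[, 4] * r2))^2
  ii - (d1 + d2) / (img_w^2 + img_h^2)
}
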