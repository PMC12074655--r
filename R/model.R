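# Full detector assembly and training: backbone -> hybrid encoder ->
# encoder prediction heads (IoU-aware query selection) -> decoder with
# denoising groups -> Hungarian-matched losses. Sized for desk-scale
# experiments: every piece is the real mechanism, run small.

#' Detector configuration
#'
#' @param input_side square input side (divisible by 32).
#' @param n_classes foreground class count.
#' @param backbone a [backbone_config()].
#' @param encoder an [encoder_config()].
#' @param decoder a [decoder_config()].
#' @param loss_weights named vector `cls`, `l1`, `iou` used in both the
#'   Hungarian matching cost and the loss (DETR-family convention 2/5/2).
#' @param iou_ratio interior-emphasis ratio of IACD-IoU (0.7).
#' @param corner_mode corner flavour of the IACD-IoU penalty.
#' @param label_flip_p,box_noise_scale,n_dn_groups denoising settings
#'   (DN-DETR conventions 0.5 / 0.4 / 5).
#' @param seed integer seed.
#' @return an `osdetr_config` list.
#' @export
osdetr_config <- function(input_side = 160L, n_classes = 1L,
                          backbone = backbone_config(),
                          encoder = encoder_config(hidden_dim = 64L),
                          decoder = decoder_config(dim = 64L),
                          loss_weights = c(cls = 2, l1 = 5, iou = 2),
                          iou_ratio = 0.7, corner_mode = "scaled",
                          label_flip_p = 0.5, box_noise_scale = 0.4,
                          n_dn_groups = 5L, seed = 0L) {
  stopifnot(input_side %% 32L == 0L,
            encoder$hidden_dim == decoder$dim)
  structure(list(input_side = as.integer(input_side),
                 n_classes = as.integer(n_classes),
                 backbone = backbone, encoder = encoder, decoder = decoder,
                 loss_weights = loss_weights, iou_ratio = iou_ratio,
                 corner_mode = corner_mode, label_flip_p = label_flip_p,
                 box_noise_scale = box_noise_scale,
                 n_dn_groups = as.integer(n_dn_groups),
                 seed = as.integer(seed)),
            class = "osdetr_config")
}

#' Assemble an OS-DETR style detector
#' @param cfg an [osdetr_config()].
#' @return an `osdetr` model list (modules, heads, parameter index).
#' @export
build_osdetr <- function(cfg) {
  hd <- cfg$encoder$hidden_dim
  backbone <- build_backbone(cfg$backbone)
  encoder <- build_encoder(cfg$backbone$stage_channels, cfg$encoder)
  dec_par <- decoder_params(cfg$decoder)
  enc_heads <- with_seed(cfg$seed + 7L, list(
    memory_ln = ln_param(hd),
    class_head = linear_param(hd, cfg$n_classes, gain = 0.1),
    box_head = linear_param(hd, 4L, gain = 0.1)))
  model <- list(cfg = cfg, backbone = backbone, encoder = encoder,
                decoder = dec_par, enc_heads = enc_heads)
  model$params <- collect_params(list(backbone = backbone$params,
                                      stages = backbone$stages,
                                      encoder = encoder$params,
                                      decoder = dec_par,
                                      enc_heads = enc_heads))
  class(model) <- "osdetr"
  model
}

logit <- function(p, eps = 1e-4) {
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

# normalized (cx, cy, w, h) anchors for every token of the three scales
token_anchors <- function(sides) {
  do.call(rbind, lapply(seq_along(sides), function(s) {
    n <- sides[s]
    g <- make_reference_grid(n, n, 1L)$flat     # [-1, 1]
    pos <- (g + 1) / 2
    wh <- min(1, 4 / n)           # size prior tied to the scale's stride
    cbind(pos[, 1L], pos[, 2L], wh, wh)
  }))
}

# run backbone + encoder, return per-image memory and encoder predictions
osdetr_encode <- function(model, images, training = TRUE) {
  cfg <- model$cfg
  feats <- backbone_forward(model$backbone, images, training)
  fused <- encoder_forward(model$encoder, feats)
  sides <- vapply(fused, function(f) dim(ag_value(f))[3L], 1L)
  anchors <- token_anchors(sides)
  bsz <- dim(ag_value(images))[1L]
  lapply(seq_len(bsz), function(i) {
    # layer-normalized memory: keeps the prediction heads and the decoder
    # in a stable numeric range regardless of encoder feature scale
    mem <- lapply(1:3, function(s) list(
      tokens = ag_layernorm(fmap_tokens(fused[[s]], i),
                            model$enc_heads$memory_ln$gamma,
                            model$enc_heads$memory_ln$beta),
      H = sides[s], W = sides[s]))
    tok_all <- ag_rbind(lapply(mem, `[[`, "tokens"))
    enc_logits <- ag_linear(tok_all, model$enc_heads$class_head$W,
                            model$enc_heads$class_head$b)
    enc_box_logit <- ag_add(ag_linear(tok_all, model$enc_heads$box_head$W,
                                      model$enc_heads$box_head$b),
                            ag_const(logit(anchors)))
    list(memory = mem, tokens = tok_all, enc_logits = enc_logits,
         enc_boxes = ag_sigmoid(enc_box_logit))
  })
}

# initial matching queries from the encoder predictions (content and boxes
# are detached: the encoder is supervised through its own auxiliary loss)
init_queries <- function(enc, k) {
  scores <- 1 / (1 + exp(-ag_value(enc$enc_logits)))
  idx <- iou_aware_query_select(scores, k)
  list(idx = idx,
       content = ag_const(ag_value(enc$tokens)[idx, , drop = FALSE]),
       coords_logit = ag_const(logit(ag_value(enc$enc_boxes)[idx, ,
                                                             drop = FALSE],
                               eps = 0.01)))
}

match_and_losses <- function(out, gt_boxes, gt_classes, cfg) {
  # Hungarian matching + the three loss terms for one layer's output
  w <- cfg$loss_weights
  scores <- 1 / (1 + exp(-ag_value(out$logits)))
  m <- hungarian_match(ag_value(out$boxes), scores, gt_boxes, gt_classes,
                       weights = w, ratio = cfg$iou_ratio)
  k <- nrow(ag_value(out$logits))
  # IoU-aware classification targets: a matched query is supervised toward
  # the IoU of its own predicted box, so score learns to rank localization
  # quality; background entries carry the conventional 0.1 weight
  pbv <- ag_value(out$boxes)[m$pred, , drop = FALSE]
  gbv <- as.matrix(as.data.frame(gt_boxes))[m$gt, 1:4, drop = FALSE]
  ious <- pmax(iou_mat(pbv, gbv), 0.05)
  tgt <- matrix(0, k, cfg$n_classes)
  tgt[cbind(m$pred, gt_classes[m$gt])] <- ious
  wm <- matrix(0.1, k, cfg$n_classes)
  wm[cbind(m$pred, gt_classes[m$gt])] <- 1
  cls <- ag_bce_logits(out$logits, tgt, wm)
  pb <- ag_rows(out$boxes, m$pred)
  gb <- as.matrix(as.data.frame(gt_boxes))[m$gt, 1:4, drop = FALSE]
  l1 <- ag_mean(ag_abs(ag_sub(pb, gb)))
  iacd <- ag_iacd_loss(pb, gb, ratio = cfg$iou_ratio,
                       corner_mode = cfg$corner_mode)
  list(cls = cls, l1 = l1, iacd = iacd)
}

weighted_total <- function(terms, w) {
  tot <- NULL
  for (t in terms) {
    contrib <- ag_add(ag_add(ag_scale(t$cls, unname(w["cls"])),
                             ag_scale(t$l1, unname(w["l1"]))),
                      ag_scale(t$iacd, unname(w["iou"])))
    tot <- if (is.null(tot)) contrib else ag_add(tot, contrib)
  }
  tot
}

#' One training step on a batch of scenes
#'
#' Full forward (backbone, encoder, query selection, denoising groups,
#' decoder), Hungarian-matched classification + L1 + IACD-IoU losses at
#' every decoder layer, denoising reconstruction losses with a fixed
#' assignment, and the encoder's IoU-aware auxiliary loss; one optimizer
#' update.
#'
#' @param model an `osdetr` model.
#' @param scenes list of scenes (`image` matrix plus `boxes` data frame
#'   with `x, y, w, h, class_id` in pixels) — from [generate_scenes()].
#' @param opt optimizer from [adam()] over `model$params`.
#' @param step_seed integer seed for the denoising noise of this step.
#' @return named numeric vector of loss components (`total`, `cls`, `l1`,
#'   `iacd`, `dn`, `enc`).
#' @export
train_step <- function(model, scenes, opt, step_seed = 0L) {
  cfg <- model$cfg
  if (!length(scenes)) stop("empty batch")
  side <- cfg$input_side
  bsz <- length(scenes)
  images <- array(0, c(bsz, 1L, side, side))
  for (i in seq_len(bsz)) images[i, 1L, , ] <- scenes[[i]]$image
  encs <- osdetr_encode(model, images, training = TRUE)
  total <- NULL
  comp <- c(cls = 0, l1 = 0, iacd = 0, dn = 0, enc = 0)
  w <- cfg$loss_weights
  for (i in seq_len(bsz)) {
    gtb <- scenes[[i]]$boxes
    if (!nrow(gtb)) next
    gt_boxes <- data.frame(cx = (gtb$x + gtb$w / 2) / side,
                           cy = (gtb$y + gtb$h / 2) / side,
                           w = gtb$w / side, h = gtb$h / side)
    gt_classes <- gtb$class_id
    ng <- nrow(gt_boxes)
    q <- init_queries(encs[[i]], cfg$decoder$n_queries)
    dn <- add_denoising_noise(gt_boxes, gt_classes, cfg$n_classes,
                              cfg$label_flip_p, cfg$box_noise_scale,
                              cfg$n_dn_groups,
                              seed = step_seed * 1000L + i)
    dn_content <- ag_rows(model$decoder$label_emb,
                          unlist(lapply(dn, function(g) g$classes + 1L)))
    dn_coords <- ag_const(logit(do.call(rbind,
                                        lapply(dn, function(g) g$boxes))))
    n_match <- length(q$idx)
    mask <- denoising_attn_mask(n_match, rep(ng, cfg$n_dn_groups))
    content <- ag_rbind(list(q$content, dn_content))
    coords <- ag_rbind(list(q$coords_logit, dn_coords))
    outs <- decoder_forward(content, coords,
                            encs[[i]]$memory, model$decoder, cfg$decoder,
                            mask = mask)
    match_rows <- seq_len(n_match)
    dn_rows <- n_match + seq_len(ng * cfg$n_dn_groups)
    layer_terms <- list(); dn_terms <- list()
    for (l in seq_along(outs)) {
      o <- outs[[l]]
      o_match <- list(logits = ag_rows(o$logits, match_rows),
                      boxes = ag_rows(o$boxes, match_rows))
      layer_terms[[l]] <- match_and_losses(o_match, gt_boxes, gt_classes, cfg)
      # denoising queries reconstruct their source gt (fixed assignment)
      dn_tgt <- matrix(0, length(dn_rows), cfg$n_classes)
      src <- rep(seq_len(ng), times = cfg$n_dn_groups)
      dn_tgt[cbind(seq_along(src), gt_classes[src])] <- 1
      dn_w <- matrix(0.1, length(dn_rows), cfg$n_classes)
      dn_w[dn_tgt > 0] <- 1
      dlog <- ag_rows(o$logits, dn_rows)
      dbox <- ag_rows(o$boxes, dn_rows)
      gb <- as.matrix(gt_boxes)[src, , drop = FALSE]
      dn_terms[[l]] <- list(cls = ag_bce_logits(dlog, dn_tgt, dn_w),
                            l1 = ag_mean(ag_abs(ag_sub(dbox, gb))),
                            iacd = ag_iacd_loss(dbox, gb,
                                                ratio = cfg$iou_ratio,
                                                corner_mode = cfg$corner_mode))
    }
    # encoder auxiliary loss: matched tokens supervised toward the IoU of
    # their predicted box with the assigned gt (IoU-aware), others toward 0
    enc <- encs[[i]]
    escores <- 1 / (1 + exp(-ag_value(enc$enc_logits)))
    eb <- ag_value(enc$enc_boxes)
    em <- hungarian_match(eb, escores, gt_boxes, gt_classes,
                          weights = w, ratio = cfg$iou_ratio)
    etgt <- matrix(0, nrow(eb), cfg$n_classes)
    pred_df <- data.frame(cx = eb[em$pred, 1], cy = eb[em$pred, 2],
                          w = eb[em$pred, 3], h = eb[em$pred, 4])
    ious <- iou_cxcywh(pred_df, gt_boxes[em$gt, , drop = FALSE])
    etgt[cbind(em$pred, gt_classes[em$gt])] <- pmax(ious, 0.01)
    ew <- matrix(0.1, nrow(eb), cfg$n_classes)
    ew[cbind(em$pred, gt_classes[em$gt])] <- 1
    enc_terms <- list(list(
      cls = ag_bce_logits(enc$enc_logits, etgt, ew),
      l1 = ag_mean(ag_abs(ag_sub(ag_rows(enc$enc_boxes, em$pred),
                                 as.matrix(gt_boxes)[em$gt, , drop = FALSE]))),
      iacd = ag_iacd_loss(ag_rows(enc$enc_boxes, em$pred),
                          as.matrix(gt_boxes)[em$gt, , drop = FALSE],
                          ratio = cfg$iou_ratio,
                          corner_mode = cfg$corner_mode)))
    t_match <- weighted_total(layer_terms, w)
    t_dn <- weighted_total(dn_terms, w)
    t_enc <- weighted_total(enc_terms, w)
    img_total <- ag_add(ag_add(t_match, t_dn), t_enc)
    total <- if (is.null(total)) img_total else ag_add(total, img_total)
    comp["cls"] <- comp["cls"] + sum(vapply(layer_terms,
                                            function(t) ag_value(t$cls), 1.0))
    comp["l1"] <- comp["l1"] + sum(vapply(layer_terms,
                                          function(t) ag_value(t$l1), 1.0))
    comp["iacd"] <- comp["iacd"] + sum(vapply(layer_terms,
                                              function(t) ag_value(t$iacd), 1.0))
    comp["dn"] <- comp["dn"] + ag_value(t_dn)
    comp["enc"] <- comp["enc"] + ag_value(t_enc)
  }
  if (is.null(total)) stop("batch contained no ground-truth boxes")
  total <- ag_scale(total, 1 / bsz)
  ag_zero_grad(opt$params)
  ag_backward(total)
  adam_step(opt, clip = 5)
  c(total = unname(ag_value(total)), comp / bsz)
}

#' Train a detector on a fixed set of scenes
#'
#' Minibatches cycle deterministically through the scene list; the learning
#' rate decays once (by `lr_decay_factor` at `lr_decay_step`), which settles
#' the Hungarian assignments late in training. With `eval_every > 0` the
#' training-set mAP@50 is measured periodically and training stops early
#' once `target_map50` is reached.
#'
#' @param model an `osdetr` model.
#' @param scenes training scenes.
#' @param steps maximum optimizer steps.
#' @param lr Adam learning rate.
#' @param batch_size scenes per step (capped at the scene count).
#' @param lr_decay_step,lr_decay_factor one-step learning-rate decay.
#' @param eval_every evaluate training mAP every this many steps (0 = never).
#' @param target_map50 early-stop threshold on training mAP@50.
#' @param score_thr detection threshold used for the periodic evaluation.
#' @param verbose print the loss every 25 steps.
#' @return data frame of per-step loss components, with attribute
#'   `map50` holding the last measured training mAP (if evaluated).
#' @export
osdetr_train <- function(model, scenes, steps = 300L, lr = 2e-3,
                         batch_size = 8L, lr_decay_step = 200L,
                         lr_decay_factor = 0.25, eval_every = 0L,
                         target_map50 = NULL, score_thr = 0.1,
                         verbose = FALSE) {
  opt <- adam(model$params, lr = lr)
  n <- length(scenes)
  bs <- min(batch_size, n)
  log <- vector("list", steps)
  last_map <- NA_real_
  used <- 0L
  for (s in seq_len(steps)) {
    if (s == lr_decay_step) opt$lr <- opt$lr * lr_decay_factor
    idx <- ((used + seq_len(bs) - 1L) %% n) + 1L
    used <- (used + bs) %% n
    losses <- train_step(model, scenes[idx], opt, step_seed = s)
    log[[s]] <- c(step = s, losses)
    if (verbose && s %% 25L == 0L)
      message(sprintf("step %d  total %.4f", s, losses["total"]))
    if (eval_every > 0L && s %% eval_every == 0L && s >= eval_every * 2L) {
      last_map <- osdetr_evaluate(model, scenes, score_thr)$map50
      if (verbose) message(sprintf("  training mAP@50 %.3f", last_map))
      if (!is.null(target_map50) && last_map >= target_map50) break
    }
  }
  out <- as.data.frame(do.call(rbind, log[!vapply(log, is.null, TRUE)]))
  attr(out, "map50") <- last_map
  out
}

#' Detect lesions in one image
#'
#' Runs the full model and thresholds the final decoder layer's scores;
#' the set prediction is end-to-end, so no non-maximum suppression is
#' applied.
#'
#' @param model a trained `osdetr` model.
#' @param image matrix `(side, side)` in `[0, 1]`.
#' @param score_thr detection score threshold.
#' @return data frame `cx, cy, w, h, score, class_id` in absolute pixels.
#' @export
detect <- function(model, image, score_thr = 0.5) {
  cfg <- model$cfg
  side <- cfg$input_side
  images <- array(image, c(1L, 1L, side, side))
  enc <- osdetr_encode(model, images, training = FALSE)[[1L]]
  q <- init_queries(enc, cfg$decoder$n_queries)
  outs <- decoder_forward(q$content, q$coords_logit, enc$memory,
                          model$decoder, cfg$decoder)
  fin <- outs[[length(outs)]]
  probs <- 1 / (1 + exp(-ag_value(fin$logits)))
  cls <- max.col(probs, ties.method = "first")
  sc <- probs[cbind(seq_len(nrow(probs)), cls)]
  keep <- sc >= score_thr
  b <- ag_value(fin$boxes)[keep, , drop = FALSE] * side
  data.frame(cx = b[, 1], cy = b[, 2], w = b[, 3], h = b[, 4],
             score = sc[keep], class_id = cls[keep])
}

#' Evaluate a model on scenes
#' @param model a trained `osdetr` model.
#' @param scenes list of scenes with ground-truth boxes.
#' @param score_thr score threshold passed to [detect()].
#' @return list with `map50`, `map5095`, `dets`, `gts`.
#' @export
osdetr_evaluate <- function(model, scenes, score_thr = 0.1) {
  dets <- list(); gts <- list()
  for (i in seq_along(scenes)) {
    d <- detect(model, scenes[[i]]$image, score_thr)
    if (nrow(d)) dets[[length(dets) + 1L]] <- cbind(image_id = i, d)
    g <- scenes[[i]]$boxes
    if (nrow(g))
      gts[[length(gts) + 1L]] <- data.frame(
        image_id = i, class_id = g$class_id,
        cx = g$x + g$w / 2, cy = g$y + g$h / 2, w = g$w, h = g$h)
  }
  dets <- if (length(dets)) do.call(rbind, dets)
          else data.frame(image_id = integer(), class_id = integer(),
                          cx = numeric(), cy = numeric(), w = numeric(),
                          h = numeric(), score = numeric())
  gts <- do.call(rbind, gts)
  m <- map_range(dets, gts)
  list(map50 = m[["map50"]], map5095 = m[["map5095"]], dets = dets,
       gts = gts)
}

#' Save / load detector weights
#'
#' Checkpoint = flat little-endian double array of all parameters plus a
#' JSON sidecar recording the parameter names and lengths.
#'
#' @param model an `osdetr` model.
#' @param path checkpoint path (sidecar at `path` + `".json"`).
#' @return invisibly `path`; `load_osdetr_weights` returns the model with
#'   weights restored in place.
#' @name osdetr-io
NULL

#' @rdname osdetr-io
#' @export
save_osdetr_weights <- function(model, path) {
  vals <- lapply(model$params, function(p) as.numeric(p$value))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(unlist(vals), con, size = 8L, endian = "little")
  jsonlite::write_json(list(names = names(model$params),
                            lengths = vapply(vals, length, 1L)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname osdetr-io
#' @export
load_osdetr_weights <- function(model, path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = sum(meta$lengths), size = 8L,
                  endian = "little")
  off <- 0L
  for (i in seq_along(meta$names)) {
    p <- model$params[[meta$names[i]]]
    if (is.null(p)) stop("checkpoint parameter missing in model: ",
                         meta$names[i])
    p$value[] <- vals[off + seq_len(meta$lengths[i])]
    off <- off + meta$lengths[i]
  }
  invisible(model)
}
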