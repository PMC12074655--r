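# Synthetic lesion scenes: smooth noisy background, an optional bright
# ring mimicking a skull outline, and high-intensity elliptical lesions
# with soft (blurred) edges. Ground-truth boxes are tight axis-aligned
# bounds of the rendered above-threshold lesion mask. The box-size
# distribution is tuned so the bulk of boxes cover well under 20% of the
# image, matching the size profile typical of brain-tumor detection data.
# No anatomical realism is attempted: the point is a learnable, fully
# reproducible detection signal.

#' Synthetic-dataset configuration
#'
#' @param n_images number of scenes.
#' @param image_side square image side in pixels.
#' @param lesions_range integer range (min, max) of lesions per scene.
#' @param noise_sd Gaussian background noise standard deviation (intensity
#'   units; images live in `[0, 1]`).
#' @param intensity_offset lesion brightness above the local background.
#' @param semiaxis_range lesion semi-axes as a fraction of the image side.
#' @param skull_ring draw a bright ring near the image border.
#' @param max_box_area_fraction reject lesions whose tight box exceeds this
#'   fraction of the image area.
#' @param edge_softness lesion edge width in pixels (soft sigmoid falloff).
#' @param seed integer seed; every output is a pure function of
#'   `(cfg, seed)`.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_images = 16L, image_side = 160L,
                         lesions_range = c(1L, 3L), noise_sd = 0.04,
                         intensity_offset = 0.4,
                         semiaxis_range = c(0.05, 0.16),
                         skull_ring = TRUE, max_box_area_fraction = 0.2,
                         edge_softness = 1.5, seed = 0L) {
  if (max_box_area_fraction <= 0 || max_box_area_fraction > 1)
    stop("max_box_area_fraction must be in (0, 1]")
  structure(list(n_images = as.integer(n_images),
                 image_side = as.integer(image_side),
                 lesions_range = as.integer(lesions_range),
                 noise_sd = noise_sd, intensity_offset = intensity_offset,
                 semiaxis_range = semiaxis_range,
                 skull_ring = isTRUE(skull_ring),
                 max_box_area_fraction = max_box_area_fraction,
                 edge_softness = edge_softness, seed = as.integer(seed)),
            class = "synth_config")
}

# soft ellipse membership in [0, 1]; rho = 1 is the nominal rim
ellipse_alpha <- function(px, py, spec, edge) {
  ct <- cos(spec$angle); st <- sin(spec$angle)
  dx <- px - spec$cx; dy <- py - spec$cy
  xr <- dx * ct + dy * st
  yr <- -dx * st + dy * ct
  rho <- sqrt((xr / spec$a)^2 + (yr / spec$b)^2)
  scale <- edge / max(spec$a, spec$b)
  1 / (1 + exp((rho - 1) / max(scale, 1e-6)))
}

#' Render one synthetic scene
#'
#' @param cfg a [synth_config()].
#' @param seed integer seed for this scene.
#' @return list with `image` (side x side matrix in `[0, 1]`, row = y),
#'   `lesions` (data frame of ellipse specs: `cx, cy, a, b, angle,
#'   intensity, class_id`), and `boxes` (data frame `x, y, w, h, class_id`
#'   — tight COCO-style boxes, 0-based continuous pixel coordinates).
#' @export
render_scene <- function(cfg, seed = cfg$seed) {
  with_seed(seed, {
    side <- cfg$image_side
    # pixel (row i, col j) has center (x, y) = (j - 0.5, i - 0.5)
    px <- matrix(seq_len(side) - 0.5, side, side, byrow = TRUE)
    py <- matrix(seq_len(side) - 0.5, side, side)
    fx <- stats::runif(1, 0.5, 1.5) * pi / side
    fy <- stats::runif(1, 0.5, 1.5) * pi / side
    phx <- stats::runif(1, 0, 2 * pi); phy <- stats::runif(1, 0, 2 * pi)
    img <- 0.3 + 0.06 * cos(fx * px + phx) * cos(fy * py + phy) +
      matrix(stats::rnorm(side * side, sd = cfg$noise_sd), side, side)
    if (cfg$skull_ring) {
      rr <- sqrt((px - side / 2)^2 + (py - side / 2)^2)
      ring <- exp(-((rr - 0.44 * side)^2) / (2 * (0.015 * side)^2))
      img <- img + 0.25 * ring
    }
    n_les <- if (cfg$lesions_range[1] == cfg$lesions_range[2])
      cfg$lesions_range[1]
    else sample(cfg$lesions_range[1]:cfg$lesions_range[2], 1L)
    lesions <- list(); boxes <- list()
    for (k in seq_len(n_les)) {
      placed <- FALSE
      for (try_ in 1:50) {
        a <- stats::runif(1, cfg$semiaxis_range[1], cfg$semiaxis_range[2]) * side
        b <- stats::runif(1, cfg$semiaxis_range[1], cfg$semiaxis_range[2]) * side
        ang <- stats::runif(1, 0, pi)
        ext <- sqrt((a * cos(ang))^2 + (b * sin(ang))^2)
        eyt <- sqrt((a * sin(ang))^2 + (b * cos(ang))^2)
        margin <- 2 * cfg$edge_softness
        cx <- stats::runif(1, ext + margin, side - ext - margin)
        cy <- stats::runif(1, eyt + margin, side - eyt - margin)
        if ((2 * ext) * (2 * eyt) > cfg$max_box_area_fraction * side^2) next
        spec <- list(cx = cx, cy = cy, a = a, b = b, angle = ang,
                     intensity = cfg$intensity_offset)
        alpha <- ellipse_alpha(px, py, spec, cfg$edge_softness)
        mask <- alpha > 0.5
        if (!any(mask)) next
        cols <- range(which(apply(mask, 2L, any)))
        rows <- range(which(apply(mask, 1L, any)))
        bx <- cols[1] - 1; bw <- cols[2] - cols[1] + 1
        by <- rows[1] - 1; bh <- rows[2] - rows[1] + 1
        if (bw * bh > cfg$max_box_area_fraction * side^2) next
        img <- img + spec$intensity * alpha
        lesions[[length(lesions) + 1L]] <-
          data.frame(cx = cx, cy = cy, a = a, b = b, angle = ang,
                     intensity = spec$intensity, class_id = 1L)
        boxes[[length(boxes) + 1L]] <-
          data.frame(x = bx, y = by, w = bw, h = bh, class_id = 1L)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place lesion ", k, " after bounded retries; ",
             "loosen semiaxis_range or max_box_area_fraction")
    }
    img <- pmin(pmax(img, 0), 1)
    list(image = img,
         lesions = if (length(lesions)) do.call(rbind, lesions)
                   else data.frame(cx = numeric(), cy = numeric(),
                                   a = numeric(), b = numeric(),
                                   angle = numeric(), intensity = numeric(),
                                   class_id = integer()),
         boxes = if (length(boxes)) do.call(rbind, boxes)
                 else data.frame(x = numeric(), y = numeric(), w = numeric(),
                                 h = numeric(), class_id = integer()))
  })
}

#' Generate a list of in-memory scenes
#' @param cfg a [synth_config()].
#' @return list of [render_scene()] results, scene `i` seeded
#'   `cfg$seed + i`.
#' @export
generate_scenes <- function(cfg) {
  lapply(seq_len(cfg$n_images), function(i) render_scene(cfg, cfg$seed + i))
}

#' Write a synthetic dataset to disk
#'
#' PNG images plus COCO-JSON annotations (`annotations.json`; boxes as
#' `[x, y, w, h]` in absolute 0-based continuous pixels) and an optional
#' YOLO-txt mirror (`labels/<image>.txt` with
#' `class cx cy w h` normalized to (0,1), 0-based class ids).
#'
#' @param cfg a [synth_config()].
#' @param dir output directory (created if missing).
#' @param yolo also write the YOLO-txt mirror.
#' @return invisibly, the annotation list.
#' @export
generate_dataset <- function(cfg, dir, yolo = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scenes <- generate_scenes(cfg)
  images <- list(); anns <- list(); aid <- 0L
  if (yolo) dir.create(file.path(dir, "labels"), showWarnings = FALSE)
  for (i in seq_along(scenes)) {
    fn <- sprintf("img_%04d.png", i)
    png::writePNG(scenes[[i]]$image, file.path(dir, fn))
    images[[i]] <- list(id = i, file_name = fn,
                        width = cfg$image_side, height = cfg$image_side)
    bx <- scenes[[i]]$boxes
    ylines <- character(0)
    for (j in seq_len(nrow(bx))) {
      aid <- aid + 1L
      anns[[aid]] <- list(id = aid, image_id = i,
                          category_id = bx$class_id[j],
                          bbox = c(bx$x[j], bx$y[j], bx$w[j], bx$h[j]),
                          area = bx$w[j] * bx$h[j], iscrowd = 0L)
      ylines <- c(ylines, sprintf("%d %.6f %.6f %.6f %.6f",
                                  bx$class_id[j] - 1L,
                                  (bx$x[j] + bx$w[j] / 2) / cfg$image_side,
                                  (bx$y[j] + bx$h[j] / 2) / cfg$image_side,
                                  bx$w[j] / cfg$image_side,
                                  bx$h[j] / cfg$image_side))
    }
    if (yolo)
      writeLines(ylines, file.path(dir, "labels",
                                   sub("\\.png$", ".txt", fn)))
  }
  coco <- list(images = images, annotations = anns,
               categories = list(list(id = 1L, name = "lesion")))
  write_coco(coco, file.path(dir, "annotations.json"))
  invisible(coco)
}

#' Classification variant for the orthogonality ablation
#'
#' Balanced two-class image set: class 1 scenes contain a lesion, class 0
#' scenes are pure background, rendered with the same generator.
#'
#' @param cfg a [synth_config()]; `n_images` is the total count (split
#'   evenly; must be even).
#' @return list with `images` (array `(n, side, side)`), `labels`
#'   (integer 0/1).
#' @export
small_classification_variant <- function(cfg) {
  if (cfg$n_images %% 2L != 0L) stop("n_images must be even for balance")
  half <- cfg$n_images %/% 2L
  pos_cfg <- cfg; pos_cfg$lesions_range <- c(1L, 1L)
  neg_cfg <- cfg; neg_cfg$lesions_range <- c(0L, 0L)
  side <- cfg$image_side
  imgs <- array(0, c(cfg$n_images, side, side))
  labels <- integer(cfg$n_images)
  for (i in seq_len(half)) {
    imgs[i, , ] <- render_scene(pos_cfg, cfg$seed + i)$image
    labels[i] <- 1L
    imgs[half + i, , ] <- render_scene(neg_cfg, cfg$seed + 10000L + i)$image
    labels[half + i] <- 0L
  }
  list(images = imgs, labels = labels)
}

#' Class-balanced nested fraction subsets
#'
#' Returns indices of a `fraction` subset that preserves class balance;
#' for a fixed seed the subsets are nested
#' (10% of the data is contained in the 20% subset, and so on), because
#' each class is put in one fixed seeded order and prefixes are taken.
#'
#' @param labels class labels.
#' @param fraction value in (0, 1].
#' @param seed integer seed fixing the per-class order.
#' @return integer indices into `labels`.
#' @export
subset_fraction <- function(labels, fraction, seed = 0L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  idx <- with_seed(seed, {
    out <- integer(0)
    for (cl in sort(unique(labels))) {
      pool <- sample(which(labels == cl))
      k <- round(fraction * length(pool))
      if (k < 1)
        stop("fraction ", fraction, " leaves no samples for class ", cl)
      out <- c(out, pool[seq_len(k)])
    }
    out
  })
  sort(idx)
}
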