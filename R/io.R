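# Annotation and results I/O. COCO-JSON is the primary dialect: boxes are
# [x, y, w, h] in absolute 0-based continuous pixel coordinates; the
# YOLO-txt mirror stores `class cx cy w h` normalized to (0,1).

#' Write / read COCO-JSON annotations
#'
#' @param coco list with `images`, `annotations`, `categories` in the
#'   standard COCO layout.
#' @param path JSON file path.
#' @return `write_coco` invisibly returns `path`; `read_coco` returns the
#'   annotation list.
#' @name coco-io
NULL

#' @rdname coco-io
#' @export
write_coco <- function(coco, path) {
  boxit <- function(x) {
    x$bbox <- I(as.numeric(x$bbox))
    x
  }
  coco$annotations <- lapply(coco$annotations, boxit)
  jsonlite::write_json(coco, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname coco-io
#' @export
read_coco <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Ground-truth boxes of one image from a COCO annotation list
#' @param coco COCO list.
#' @param image_id image id.
#' @return data frame `x, y, w, h, class_id` (COCO corner-size form).
#' @export
coco_boxes <- function(coco, image_id) {
  rows <- Filter(function(a) a$image_id == image_id, coco$annotations)
  if (!length(rows))
    return(data.frame(x = numeric(), y = numeric(), w = numeric(),
                      h = numeric(), class_id = integer()))
  do.call(rbind, lapply(rows, function(a)
    data.frame(x = a$bbox[[1]], y = a$bbox[[2]], w = a$bbox[[3]],
               h = a$bbox[[4]], class_id = a$category_id)))
}

#' Convert COCO corner-size boxes to center-size form
#' @param df data frame `x, y, w, h` (plus extra columns, preserved).
#' @return data frame with `cx, cy, w, h` (extras preserved).
#' @export
xywh_to_cxcywh <- function(df) {
  out <- df
  out$cx <- df$x + df$w / 2
  out$cy <- df$y + df$h / 2
  out$x <- NULL; out$y <- NULL
  out[, c("cx", "cy", "w", "h",
          setdiff(names(out), c("cx", "cy", "w", "h")))]
}

#' Read a YOLO-txt label file
#' @param path label file (`class cx cy w h`, normalized).
#' @param image_w,image_h image extent for denormalization.
#' @return data frame `cx, cy, w, h, class_id` in absolute pixels
#'   (class ids shifted to 1-based).
#' @export
read_yolo <- function(path, image_w, image_h) {
  if (!file.exists(path) || file.size(path) == 0)
    return(data.frame(cx = numeric(), cy = numeric(), w = numeric(),
                      h = numeric(), class_id = integer()))
  m <- utils::read.table(path)
  data.frame(cx = m[[2]] * image_w, cy = m[[3]] * image_h,
             w = m[[4]] * image_w, h = m[[5]] * image_h,
             class_id = as.integer(m[[1]]) + 1L)
}

#' Load a generated dataset directory
#' @param dir directory written by [generate_dataset()].
#' @return list of scenes: `image` matrix, `boxes` data frame
#'   (`x, y, w, h, class_id`), `file_name`, `image_id`.
#' @export
load_dataset <- function(dir) {
  coco <- read_coco(file.path(dir, "annotations.json"))
  lapply(coco$images, function(im) {
    img <- png::readPNG(file.path(dir, im$file_name))
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    list(image = img, boxes = coco_boxes(coco, im$id),
         file_name = im$file_name, image_id = im$id)
  })
}

#' Write detection results in COCO results-JSON dialect
#' @param dets data frame with `image_id, class_id, cx, cy, w, h, score`.
#' @param path output JSON file.
#' @return invisibly, `path`.
#' @export
write_detections <- function(dets, path) {
  recs <- lapply(seq_len(nrow(dets)), function(i) list(
    image_id = dets$image_id[i],
    category_id = dets$class_id[i],
    bbox = I(c(dets$cx[i] - dets$w[i] / 2, dets$cy[i] - dets$h[i] / 2,
               dets$w[i], dets$h[i])),
    score = dets$score[i]))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
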