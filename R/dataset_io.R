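# ---------------------------------------------------------------------------
# Dataset construction: PASCAL-VOC XML annotations (LabelImg dialect),
# dish-stratified splitting, the 12-hour temporal filter and the six-method
# photometric augmentation policy.
#
# Coordinate dialect: on disk, VOC boxes are 1-based inclusive pixel corners
# (xmin..xmax both inside the box); in memory boxes are 0-based half-open
# (x2 = one past the last pixel), so width = x2 - x1.
# ---------------------------------------------------------------------------

AUG_METHODS <- c("Add", "Multiply", "GaussianBlur", "CoarsePepper",
                 "GammaContrast", "GaussianNoise")

#' Annotation record for one image
#'
#' @param image_id image identifier (file stem)
#' @param dish_id dish number (1..16)
#' @param cell_id cell number within the dish
#' @param timestamp_h hours since sowing (multiple of 0.25)
#' @param boxes data.frame with columns x1, y1, x2, y2 (0-based half-open
#'   pixels), label in {"sprout", "not_sprout"}
#' @param width,height image size in pixels
#' @return an `annotation_record`
#' @export
annotation_record <- function(image_id, dish_id, cell_id, timestamp_h, boxes,
                              width, height) {
  if (timestamp_h < 0 || abs(timestamp_h / 0.25 - round(timestamp_h / 0.25)) > 1e-9)
    stop("timestamp must be a non-negative multiple of 0.25 h")
  if (nrow(boxes)) {
    if (!all(boxes$label %in% CLASS_LABELS))
      stop("unknown label(s): ",
           paste(setdiff(unique(boxes$label), CLASS_LABELS), collapse = ", "))
    if (any(boxes$x1 < 0 | boxes$y1 < 0 | boxes$x2 > width | boxes$y2 > height))
      stop("box outside image bounds")
  }
  structure(list(image_id = image_id, dish_id = as.integer(dish_id),
                 cell_id = as.integer(cell_id), timestamp_h = timestamp_h,
                 boxes = boxes, width = as.integer(width),
                 height = as.integer(height)),
            class = "annotation_record")
}

#' Write an annotation record as PASCAL VOC XML
#'
#' LabelImg dialect: `<annotation>` with `<size>`, one `<object>` per box
#' with `<name>` and `<bndbox>` holding 1-based inclusive corners.  Dish,
#' cell and timestamp are carried in the `<source>` element so records
#' round-trip.
#'
#' @param record an `annotation_record`
#' @param path output file
#' @export
write_voc_xml <- function(record, path) {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "images")
  xml2::xml_add_child(doc, "filename", paste0(record$image_id, ".png"))
  src <- xml2::xml_add_child(doc, "source")
  xml2::xml_add_child(src, "database", "germination")
  xml2::xml_add_child(src, "dish", as.character(record$dish_id))
  xml2::xml_add_child(src, "cell", as.character(record$cell_id))
  xml2::xml_add_child(src, "timestamp_h",
                      format(record$timestamp_h, nsmall = 2))
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(record$width))
  xml2::xml_add_child(size, "height", as.character(record$height))
  xml2::xml_add_child(size, "depth", "3")
  if (nrow(record$boxes))
    for (i in seq_len(nrow(record$boxes))) {
      b <- record$boxes[i, ]
      obj <- xml2::xml_add_child(doc, "object")
      xml2::xml_add_child(obj, "name",
                          sub("not_sprout", "not sprout", b$label))
      xml2::xml_add_child(obj, "difficult", "0")
      bb <- xml2::xml_add_child(obj, "bndbox")
      # 0-based half-open -> 1-based inclusive
      xml2::xml_add_child(bb, "xmin", as.character(round(b$x1) + 1L))
      xml2::xml_add_child(bb, "ymin", as.character(round(b$y1) + 1L))
      xml2::xml_add_child(bb, "xmax", as.character(round(b$x2)))
      xml2::xml_add_child(bb, "ymax", as.character(round(b$y2)))
    }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a PASCAL VOC XML annotation
#'
#' @param path XML file
#' @return an `annotation_record` (boxes converted to 0-based half-open)
#' @export
read_voc_xml <- function(path) {
  doc <- xml2::read_xml(path)
  num <- function(xp) as.numeric(xml2::xml_text(xml2::xml_find_first(doc, xp)))
  txt <- function(xp) xml2::xml_text(xml2::xml_find_first(doc, xp))
  width <- num(".//size/width"); height <- num(".//size/height")
  objs <- xml2::xml_find_all(doc, ".//object")
  boxes <- data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), label = character(0),
                      stringsAsFactors = FALSE)
  for (o in objs) {
    nm <- xml2::xml_text(xml2::xml_find_first(o, "./name"))
    label <- gsub("[ -]", "_", trimws(nm))
    if (!label %in% CLASS_LABELS)
      stop("unknown label in <name>: '", nm, "'")
    g <- function(f) as.numeric(xml2::xml_text(xml2::xml_find_first(
      o, paste0("./bndbox/", f))))
    boxes <- rbind(boxes, data.frame(
      x1 = g("xmin") - 1, y1 = g("ymin") - 1, x2 = g("xmax"), y2 = g("ymax"),
      label = label, stringsAsFactors = FALSE))
  }
  annotation_record(
    image_id = sub("\\.[a-zA-Z]+$", "", txt(".//filename")),
    dish_id = as.integer(txt(".//source/dish")),
    cell_id = as.integer(txt(".//source/cell")),
    timestamp_h = as.numeric(txt(".//source/timestamp_h")),
    boxes = boxes, width = width, height = height)
}

#' Dish-stratified train/test/validation split
#'
#' Whole dishes are assigned to a single split so that no dish leaks across
#' sets.  The default mapping sends dishes 1-12 to train, 13-14 to test and
#' 15-16 to validation.  `mode = "ratio"` instead assigns images to hit
#' 6:2:2 counts while still keeping stratification by interleaving
#' timestamps; both modes are provided because the dish mapping (75/12.5/12.5
#' per cent of dishes) and the printed 6:2:2 image counts are not the same
#' partition.
#'
#' @param records list of `annotation_record`s (or a manifest data.frame with
#'   columns image_id, dish_id, timestamp_h)
#' @param mode "dish" (default) or "ratio"
#' @param dish_map named list with integer vectors `train`, `test`, `val`
#' @return a `split_manifest` data.frame with columns image_id, dish_id,
#'   split
#' @export
dish_stratified_split <- function(records, mode = c("dish", "ratio"),
                                  dish_map = list(train = 1:12, test = 13:14,
                                                  val = 15:16)) {
  mode <- match.arg(mode)
  man <- records_manifest(records)
  man$split <- NULL   # re-splitting an already-split manifest
  if (any(is.na(man$dish_id))) stop("missing dish id")
  if (mode == "dish") {
    if (length(unique(man$dish_id)) == 1)
      warning("single dish: all images assigned to the training set")
    split <- rep("train", nrow(man))
    split[man$dish_id %in% dish_map$test] <- "test"
    split[man$dish_id %in% dish_map$val] <- "val"
  } else {
    # 6:2:2 by image count; round-robin over confidence-free strata
    # (dish, timestamp order) keeps class mixtures similar across sets
    n <- nrow(man)
    n_test <- round(n * 0.2); n_val <- round(n * 0.2)
    lab <- rep("train", n)
    # deterministic systematic sampling along (dish, time) order
    pos <- order(man$dish_id, man$timestamp_h, man$image_id)
    test_pos <- pos[round(seq(1, n, length.out = n_test))]
    rem <- setdiff(pos, test_pos)
    val_pos <- rem[round(seq(1, length(rem), length.out = n_val))]
    lab[test_pos] <- "test"
    lab[val_pos] <- "val"
    split <- lab
  }
  out <- cbind(man, split = split, stringsAsFactors = FALSE)
  class(out) <- c("split_manifest", "data.frame")
  out
}

records_manifest <- function(records) {
  if (is.data.frame(records)) return(as.data.frame(records))
  data.frame(
    image_id = vapply(records, function(r) r$image_id, ""),
    dish_id = vapply(records, function(r) r$dish_id, 1L),
    cell_id = vapply(records, function(r) r$cell_id %||% NA_integer_, 1L),
    timestamp_h = vapply(records, function(r) r$timestamp_h, 1),
    stringsAsFactors = FALSE)
}

#' Drop early-phase records
#'
#' Removes records captured before `cutoff_hours` (germination is not yet
#' visible early on, so those frames carry no training signal).
#'
#' @param records list of `annotation_record`s or a manifest data.frame
#' @param cutoff_hours cutoff (default 12)
#' @return filtered object of the same type
#' @export
temporal_filter <- function(records, cutoff_hours = 12) {
  if (is.data.frame(records))
    return(records[records$timestamp_h >= cutoff_hours, , drop = FALSE])
  Filter(function(r) r$timestamp_h >= cutoff_hours, records)
}

#' Photometric augmentation
#'
#' Applies one of the six photometric methods to an image (numeric array
#' (H, W, C) in `[0, 1]`).  Box geometry and labels are untouched by
#' construction.  Deterministic under a fixed seed.
#'
#' Parameter ranges: Add +/-25/255 intensity, Multiply x\[0.8, 1.2\],
#' GaussianBlur sigma \[0.5, 1.5\], CoarsePepper 2 per cent at 3 per cent
#' patch size, GammaContrast gamma \[0.7, 1.5\], GaussianNoise sigma 10/255.
#'
#' @param image numeric array (H, W, C), values in `[0, 1]`
#' @param method one of `Add`, `Multiply`, `GaussianBlur`, `CoarsePepper`,
#'   `GammaContrast`, `GaussianNoise`
#' @param seed RNG seed controlling the drawn parameter
#' @param param optional fixed method parameter (intensity for Add, factor
#'   for Multiply, sigma for GaussianBlur, gamma for GammaContrast) in place
#'   of the random draw
#' @return augmented image array, clipped to `[0, 1]`
#' @export
augment_image <- function(image, method, seed = 1L, param = NULL) {
  if (!method %in% AUG_METHODS)
    stop("unknown augmentation method '", method, "'; valid: ",
         paste(AUG_METHODS, collapse = ", "))
  set.seed(seed)
  H <- dim(image)[1]; W <- dim(image)[2]; C <- dim(image)[3]
  out <- switch(method,
    Add = image + (param %||% stats::runif(1, -25, 25)) / 255,
    Multiply = image * (param %||% stats::runif(1, 0.8, 1.2)),
    GaussianBlur = {
      sigma <- param %||% stats::runif(1, 0.5, 1.5)
      k <- 2L * ceiling(2 * sigma) + 1L
      g <- stats::dnorm(seq(-(k %/% 2), k %/% 2), sd = sigma)
      ker <- outer(g, g); ker <- ker / sum(ker)
      w <- array(0, dim = c(k, k, 1, C))
      for (ch in seq_len(C)) w[, , 1, ch] <- ker
      conv2d_hwc(image, w, numeric(0), 1L, k %/% 2L, C)
    },
    CoarsePepper = {
      frac <- 0.02; patch <- max(2L, round(0.03 * min(H, W)))
      n_patch <- max(1L, round(frac * H * W / patch^2))
      out <- image
      for (i in seq_len(n_patch)) {
        y <- sample.int(H - patch + 1L, 1)
        x <- sample.int(W - patch + 1L, 1)
        out[y:(y + patch - 1L), x:(x + patch - 1L), ] <- 0
      }
      out
    },
    GammaContrast = image^(param %||% stats::runif(1, 0.7, 1.5)),
    GaussianNoise = image + array(stats::rnorm(H * W * C, 0, 10 / 255),
                                  dim = dim(image)))
  pmin(pmax(out, 0), 1)
}

#' Build the augmented dataset manifest
#'
#' The default policy adds one augmented copy per original image, drawing the
#' method uniformly from the six under a fixed seed, so the set doubles
#' (originals retained).
#'
#' @param manifest data.frame with at least image_id (e.g. a
#'   `split_manifest`)
#' @param copies augmented copies per original
#' @param seed RNG seed for the method draw
#' @return manifest with added rows (columns `source`, `method`, `aug_seed`)
#' @export
build_dataset <- function(manifest, copies = 1L, seed = 1L) {
  man <- as.data.frame(manifest)
  if (nrow(man) == 0) {
    man$source <- character(0); man$method <- character(0)
    man$aug_seed <- integer(0)
    return(man)
  }
  man$source <- "original"
  man$method <- NA_character_
  man$aug_seed <- NA_integer_
  set.seed(seed)
  out <- man
  for (k in seq_len(copies)) {
    aug <- man
    aug$source <- "augmented"
    aug$method <- sample(AUG_METHODS, nrow(man), replace = TRUE)
    aug$aug_seed <- sample.int(.Machine$integer.max %/% 2L, nrow(man))
    aug$image_id <- paste0(man$image_id, "_aug", k)
    out <- rbind(out, aug)
  }
  rownames(out) <- NULL
  out
}
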