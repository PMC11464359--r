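#' Dataset and annotation handling
#'
#' Readers/writers for YOLO-format label files and PNG/TIFF imagery,
#' conversion of rectangle-annotation JSON (the labelme dialect) to YOLO
#' lines, and stratified train/validation splitting.
#'
#' @name dataset_io
NULL

#' Read an RGB image
#'
#' @param path PNG or TIFF file.
#' @return H x W x 3 numeric array with channels in 0-255.
#' @export
read_rgb <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  round(a * 255)
}

#' Write an RGB image as PNG (or TIFF)
#'
#' @param image H x W x 3 array, channels 0-255.
#' @param path Output file; format chosen by extension.
#' @export
write_rgb <- function(image, path) {
  assert_rgb(image)
  a <- clamp01(image / 255)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(a, path),
    tif = ,
    tiff = tiff::writeTIFF(a, path, bits.per.sample = 8L),
    stop("unsupported image format: ", ext, call. = FALSE))
  invisible(path)
}

#' Read a YOLO-format label file
#'
#' One line per box: `class x_center y_center width height`, all
#' coordinates normalized to \[0, 1\]; an optional sixth column is read as
#' `confidence` (the convention used for prediction files).
#'
#' @param path TXT file; a missing or empty file yields zero boxes.
#' @return Data frame with columns `class_id`, `x_center`, `y_center`,
#'   `width`, `height` (and `confidence` when present).
#' @export
read_yolo_labels <- function(path) {
  empty <- data.frame(class_id = integer(0), x_center = numeric(0),
                      y_center = numeric(0), width = numeric(0),
                      height = numeric(0))
  if (!file.exists(path)) return(empty)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty)
  parts <- lapply(strsplit(trimws(lines), "[[:space:]]+"), as.numeric)
  ncol <- unique(lengths(parts))
  if (length(ncol) != 1 || !(ncol %in% c(5L, 6L))) {
    stop("malformed YOLO label file: ", path, call. = FALSE)
  }
  m <- do.call(rbind, parts)
  out <- data.frame(class_id = as.integer(m[, 1]), x_center = m[, 2],
                    y_center = m[, 3], width = m[, 4], height = m[, 5])
  if (ncol == 6L) out$confidence <- m[, 6]
  out
}

#' Write boxes as a YOLO-format label file
#'
#' @param boxes Data frame with `class_id`, `x_center`, `y_center`,
#'   `width`, `height`, optionally `confidence` (written as a sixth
#'   column).
#' @param path Output TXT file.
#' @export
write_yolo_labels <- function(boxes, path) {
  if (nrow(boxes)) {
    lines <- sprintf("%d %.6f %.6f %.6f %.6f", boxes$class_id,
                     boxes$x_center, boxes$y_center, boxes$width,
                     boxes$height)
    if ("confidence" %in% names(boxes)) {
      lines <- sprintf("%s %.6f", lines, boxes$confidence)
    }
  } else {
    lines <- character(0)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Convert a rectangle-annotation JSON record to YOLO label lines
#'
#' Accepts the JSON dialect written by rectangle-labeling tools: an object
#' with `imageHeight`/`imageWidth` and a `shapes` list whose entries carry a
#' string `label` and two corner `points` in pixel coordinates (any corner
#' order). Unknown fields are ignored.
#'
#' @param record Path to a JSON file, or an already-parsed list with
#'   elements `imageHeight`, `imageWidth`, `shapes`.
#' @param class_map Named integer vector mapping labels to class ids;
#'   unlisted labels get id 0.
#' @return Character vector of YOLO label lines (also see
#'   [write_yolo_labels()]).
#' @export
convert_annotation_json_to_yolo <- function(record, class_map = c(sorghum = 0L)) {
  if (is.character(record)) record <- jsonlite::fromJSON(record, simplifyVector = FALSE)
  H <- record$imageHeight; W <- record$imageWidth
  if (is.null(H) || is.null(W)) stop("annotation record lacks image size", call. = FALSE)
  vapply(record$shapes, function(sh) {
    p <- do.call(rbind, lapply(sh$points, unlist))
    x1 <- min(p[, 1]); x2 <- max(p[, 1])
    y1 <- min(p[, 2]); y2 <- max(p[, 2])
    if (x2 <= x1 || y2 <= y1) stop("zero-area rectangle in annotation", call. = FALSE)
    cls <- if (!is.null(sh$label) && sh$label %in% names(class_map)) {
      class_map[[sh$label]]
    } else 0L
    sprintf("%d %.6f %.6f %.6f %.6f", cls,
            (x1 + x2) / 2 / W, (y1 + y2) / 2 / H,
            (x2 - x1) / W, (y2 - y1) / H)
  }, character(1))
}

#' Stratified train/validation split
#'
#' Shuffles each stratum with the given seed and assigns the first
#' ceiling(n * train/(train+val)) images to the training split, the rest to
#' validation. With the default 2:1 ratio, 36 images per stratum yield
#' 24 train / 12 validation.
#'
#' @param manifest Data frame, one row per image.
#' @param ratio Ratio string `"train:val"` (default `"2:1"`).
#' @param stratify_by Column name to stratify on (default `"altitude"`);
#'   `NULL` for a single stratum.
#' @param rng_seed Integer seed for the shuffle.
#' @return `manifest` with a `split` column (`"train"`/`"val"`), original
#'   row order preserved.
#' @export
split_dataset <- function(manifest, ratio = "2:1", stratify_by = "altitude",
                          rng_seed = 1L) {
  if (!nrow(manifest)) stop("empty manifest", call. = FALSE)
  parts <- suppressWarnings(as.integer(strsplit(ratio, ":")[[1]]))
  if (length(parts) != 2 || any(is.na(parts)) || any(parts <= 0)) {
    stop("unparseable split ratio: ", ratio, call. = FALSE)
  }
  frac <- parts[1] / sum(parts)
  strata <- if (is.null(stratify_by)) rep(1L, nrow(manifest)) else
    manifest[[stratify_by]]
  split <- character(nrow(manifest))
  with_seed(rng_seed, {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      n_train <- ceiling(length(idx) * frac)
      split[idx[seq_len(n_train)]] <- "train"
      if (n_train < length(idx)) {
        split[idx[(n_train + 1):length(idx)]] <- "val"
      } else {
        warning("stratum ", s, ": no images left for validation",
                call. = FALSE)
      }
    }
  })
  manifest$split <- split
  manifest
}

#' Convert normalized YOLO boxes to pixel corner boxes
#'
#' Boxes become half-open pixel rectangles `(x_min, y_min, x_max, y_max)`
#' in a `height_px` x `width_px` frame.
#'
#' @param boxes Data frame of normalized YOLO columns.
#' @param height_px,width_px Image size in pixels.
#' @return Data frame with corner columns (plus `class_id` and
#'   `confidence` when present).
#' @export
yolo_to_pixel <- function(boxes, height_px, width_px) {
  out <- data.frame(
    x_min = (boxes$x_center - boxes$width / 2) * width_px,
    y_min = (boxes$y_center - boxes$height / 2) * height_px,
    x_max = (boxes$x_center + boxes$width / 2) * width_px,
    y_max = (boxes$y_center + boxes$height / 2) * height_px
  )
  out$class_id <- if ("class_id" %in% names(boxes)) boxes$class_id else 0L
  if ("confidence" %in% names(boxes)) out$confidence <- boxes$confidence
  out
}

#' Convert pixel corner boxes to normalized YOLO boxes
#'
#' @param boxes Data frame with `x_min`, `y_min`, `x_max`, `y_max` (plus
#'   optional `class_id`, `confidence`).
#' @inheritParams yolo_to_pixel
#' @return Data frame of normalized YOLO columns.
#' @export
pixel_to_yolo <- function(boxes, height_px, width_px) {
  out <- data.frame(
    class_id = if ("class_id" %in% names(boxes)) boxes$class_id else 0L,
    x_center = (boxes$x_min + boxes$x_max) / 2 / width_px,
    y_center = (boxes$y_min + boxes$y_max) / 2 / height_px,
    width = (boxes$x_max - boxes$x_min) / width_px,
    height = (boxes$y_max - boxes$y_min) / height_px
  )
  if ("confidence" %in% names(boxes)) out$confidence <- boxes$confidence
  out
}
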