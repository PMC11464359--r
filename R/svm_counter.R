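#' SVM pixel classification and component counting
#'
#' The machine-learning counting path: pixels are classified into
#' plant/soil by a maximum-margin (SVM) classifier trained on patch
#' samples, the binary map is cleaned by morphological opening, and
#' 8-connected components above a minimum area are counted as seedlings,
#' each with a bounding box and a confidence.
#'
#' @name svm_counter
NULL

default_feature_config <- function() {
  list(chromatic = TRUE, indices = "EXG", mask_index = NULL)
}

# Per-pixel feature matrix: chromatic r,g,b plus configured index values;
# optionally the Otsu vegetation mask of one index as a 0/1 feature.
pixel_features <- function(image, feature_config = default_feature_config()) {
  ch <- to_chromatic(image)
  cols <- list()
  if (isTRUE(feature_config$chromatic)) {
    cols$r <- as.vector(ch$r); cols$g <- as.vector(ch$g)
    cols$b <- as.vector(ch$b)
  }
  for (nm in feature_config$indices) {
    cols[[nm]] <- as.vector(compute_index(ch, original = image, name = nm)$values)
  }
  if (!is.null(feature_config$mask_index)) {
    m <- segment(compute_index(ch, original = image,
                               name = feature_config$mask_index))
    cols[[paste0("mask_", feature_config$mask_index)]] <- as.numeric(m)
  }
  do.call(cbind, cols)
}

#' Sample labeled pixel patches from a scene
#'
#' Draws `n_patches` square patches per class: plant patches centered
#' inside ground-truth boxes, soil patches placed so they intersect no box.
#' Each patch contributes all its pixels as feature rows.
#'
#' @param image H x W x 3 RGB array.
#' @param truth A `ground_truth` object (or a data frame of normalized
#'   YOLO boxes).
#' @param n_patches Patches per class (default 15).
#' @param patch_size Patch side in pixels (default 20).
#' @param rng_seed Integer seed.
#' @param feature_config Feature layout, see [train_pixel_svm()].
#' @param refine_with_index `NULL` (default) labels every patch pixel by its
#'   patch class. Naming an index (e.g. `"EXG"`) instead refines the labels
#'   with that index's Otsu segmentation of the image: plant patches keep
#'   only segmented-vegetation pixels and soil patches only background
#'   pixels. Rosette canopies rarely fill their bounding box, so this weak
#'   labeling removes the soil pixels that would otherwise contaminate the
#'   plant class.
#' @return Object of class `pixel_sample_set`: list with `features`
#'   (n x d matrix), `labels` (factor `soil`/`sorghum`), `provenance`
#'   (patch corners) and `feature_config`.
#' @export
build_samples <- function(image, truth, n_patches = 15L, patch_size = 20L,
                          rng_seed = 1L,
                          feature_config = default_feature_config(),
                          refine_with_index = NULL) {
  assert_rgb(image)
  boxes <- if (inherits(truth, "ground_truth")) truth$boxes else truth
  if (is.null(boxes) || nrow(boxes) == 0) {
    stop("scene has no plants: cannot sample the sorghum class", call. = FALSE)
  }
  H <- dim(image)[1]; W <- dim(image)[2]
  pb <- yolo_to_pixel(boxes, H, W)
  half <- patch_size / 2
  feats <- pixel_features(image, feature_config)
  with_seed(rng_seed, {
    sample_patch_corner <- function(inside) {
      for (att in seq_len(500L)) {
        if (inside) {
          b <- sample.int(nrow(pb), 1)
          cx <- stats::runif(1, pb$x_min[b], pb$x_max[b])
          cy <- stats::runif(1, pb$y_min[b], pb$y_max[b])
        } else {
          cx <- stats::runif(1, half, W - half)
          cy <- stats::runif(1, half, H - half)
        }
        r0 <- max(1L, min(H - patch_size + 1L, round(cy - half) + 1L))
        c0 <- max(1L, min(W - patch_size + 1L, round(cx - half) + 1L))
        if (!inside) {
          hit <- any(pb$x_min < c0 + patch_size - 1 & pb$x_max > c0 - 1 &
                     pb$y_min < r0 + patch_size - 1 & pb$y_max > r0 - 1)
          if (hit) next
        }
        return(c(r0, c0))
      }
      stop("could not place a ", if (inside) "plant" else "soil",
           " patch; scene too crowded or too small", call. = FALSE)
    }
    corners_fg <- t(vapply(seq_len(n_patches),
                           function(i) sample_patch_corner(TRUE), numeric(2)))
    corners_bg <- t(vapply(seq_len(n_patches),
                           function(i) sample_patch_corner(FALSE), numeric(2)))
    patch_rows <- function(corners) {
      unlist(lapply(seq_len(nrow(corners)), function(i) {
        rows <- corners[i, 1] + seq_len(patch_size) - 1
        cols <- corners[i, 2] + seq_len(patch_size) - 1
        as.vector(outer(rows, (cols - 1) * H, `+`))
      }))
    }
    idx_fg <- patch_rows(corners_fg)
    idx_bg <- patch_rows(corners_bg)
    if (!is.null(refine_with_index)) {
      # Otsu over the pooled patch pixels (balanced classes), not the whole
      # image: with sparse vegetation a whole-image threshold sits inside
      # the soil mode
      iv <- rgb_to_index(image, refine_with_index)
      q <- quantize(iv)
      pool <- c(q$values[idx_fg], q$values[idx_bg])
      res <- otsu_threshold(matrix(pool, nrow = 1))
      if (res$degenerate) stop("no contrast in sampled patches", call. = FALSE)
      # plant exemplars only from the confident side (beyond the midpoint of
      # threshold and vegetation-class mean): mixed canopy-border pixels
      # otherwise drag the decision boundary into the soil mode
      if (iv$vegetation_polarity == "high") {
        cut_fg <- (res$T + res$mu1) / 2
        keep_fg <- q$values[idx_fg] > cut_fg
        keep_bg <- q$values[idx_bg] <= res$T
      } else {
        cut_fg <- (res$T + res$mu0) / 2
        keep_fg <- q$values[idx_fg] <= cut_fg
        keep_bg <- q$values[idx_bg] > res$T
      }
      idx_fg <- idx_fg[keep_fg]
      idx_bg <- idx_bg[keep_bg]
      if (!length(idx_fg) || !length(idx_bg)) {
        stop("index-refined labeling left a class empty", call. = FALSE)
      }
    }
    features <- rbind(feats[idx_fg, , drop = FALSE],
                      feats[idx_bg, , drop = FALSE])
    labels <- factor(rep(c("sorghum", "soil"),
                         c(length(idx_fg), length(idx_bg))),
                     levels = c("soil", "sorghum"))
    structure(list(features = features, labels = labels,
                   provenance = list(fg = corners_fg, bg = corners_bg),
                   feature_config = feature_config),
              class = "pixel_sample_set")
  })
}

#' Train the pixel-level SVM
#'
#' Fits a maximum-margin classifier on standardized pixel features; linear
#' kernel by default, radial basis available through `config$kernel`.
#'
#' @param samples A `pixel_sample_set` from [build_samples()], or any list
#'   with `features` and two-class `labels`.
#' @param config List: `kernel` (`"linear"` or `"radial"`), `cost`
#'   (default 1), `max_train` (random subsample cap on training rows,
#'   default 8000).
#' @return Object of class `pixel_model` wrapping the fitted SVM and the
#'   feature configuration.
#' @export
train_pixel_svm <- function(samples, config = list()) {
  labels <- factor(samples$labels)
  if (nlevels(labels) < 2) stop("training needs both classes", call. = FALSE)
  kernel <- config$kernel %||% "linear"
  cost <- config$cost %||% 1
  max_train <- config$max_train %||% 8000L
  X <- samples$features
  if (nrow(X) > max_train) {
    keep <- with_seed(config$subsample_seed %||% 1L,
                      sample.int(nrow(X), max_train))
    X <- X[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  fit <- e1071::svm(X, labels, kernel = kernel, cost = cost, scale = TRUE)
  # pin down which side of the hyperplane is which: predict a small mixed
  # subsample and compare classes against decision-value signs
  probe <- c(which(labels == levels(labels)[1])[1:min(25, sum(labels == levels(labels)[1]))],
             which(labels == levels(labels)[2])[1:min(25, sum(labels == levels(labels)[2]))])
  pr <- predict(fit, X[probe, , drop = FALSE], decision.values = TRUE)
  dec <- as.vector(attr(pr, "decision.values"))
  agree <- mean((dec > 0) == (as.character(pr) == "sorghum"))
  positive_level <- if (agree >= 0.5) "sorghum" else "soil"
  structure(list(fit = fit, kernel = kernel, positive_level = positive_level,
                 feature_config = samples$feature_config %||%
                   default_feature_config(),
                 feature_names = colnames(samples$features)),
            class = "pixel_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Training accuracy of a pixel model on its own samples
#'
#' @param model A `pixel_model`.
#' @param samples The `pixel_sample_set` to score.
#' @return Fraction of correctly classified rows.
#' @export
training_accuracy <- function(model, samples) {
  pred <- predict_pixels(model, samples$features)
  mean(pred == (samples$labels == "sorghum"))
}

# Classify feature rows; returns logical (TRUE = sorghum). Linear models
# use the explicit hyperplane (w.x - rho) so that whole images classify in
# one matrix product.
predict_pixels <- function(model, X) {
  fit <- model$fit
  if (model$kernel == "linear") {
    Xs <- scale(X, center = fit$x.scale$`scaled:center`,
                scale = fit$x.scale$`scaled:scale`)
    w <- crossprod(fit$SV, fit$coefs)
    dec <- as.vector(Xs %*% w) - fit$rho
    if (model$positive_level == "sorghum") dec > 0 else dec <= 0
  } else {
    as.character(predict(fit, X)) == "sorghum"
  }
}

#' Classify every pixel of an image
#'
#' @param model A `pixel_model` from [train_pixel_svm()].
#' @param image H x W x 3 RGB array.
#' @return Logical H x W mask, TRUE = plant.
#' @export
classify_pixels <- function(model, image) {
  assert_rgb(image)
  X <- pixel_features(image, model$feature_config)
  if (ncol(X) != length(model$feature_names)) {
    stop("feature dimension mismatch between model and image features",
         call. = FALSE)
  }
  matrix(predict_pixels(model, X), nrow = dim(image)[1])
}

# 8-connected labeling: EBImage's 4-connected labeling, then union of
# label pairs that touch diagonally.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1L)
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  parent <- seq_len(nlab)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  H <- nrow(lab); W <- ncol(lab)
  for (shift in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(H - 1), if (shift[2] == 1) seq_len(W - 1) else 2:W]
    b <- lab[2:H, if (shift[2] == 1) 2:W else seq_len(W - 1)]
    touch <- a > 0 & b > 0 & a != b
    if (any(touch)) {
      prs <- unique(cbind(a[touch], b[touch]))
      for (i in seq_len(nrow(prs))) {
        ra <- find(prs[i, 1]); rb <- find(prs[i, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Count plants as connected components of a binary mask
#'
#' Applies morphological opening (erosion then dilation with a square
#' structuring element), labels 8-connected components, drops those smaller
#' than `min_area_px`, and returns one detection per surviving component.
#' Confidence is `min(1, area / median(area))`, so typical-sized components
#' score 1 and fragments score proportionally lower.
#'
#' @param mask Logical H x W matrix.
#' @param min_area_px Minimum component area in pixels (>= 1).
#' @param opening_radius Radius of the square opening element; 0 disables
#'   opening.
#' @return List with `count` and `detections`, a data frame of half-open
#'   pixel boxes (`x_min`, `y_min`, `x_max`, `y_max`), `area_px` and
#'   `confidence`.
#' @export
count_components <- function(mask, min_area_px = 1L, opening_radius = 1L) {
  if (!is.logical(mask) || !is.matrix(mask)) {
    stop("mask must be a logical matrix", call. = FALSE)
  }
  stopifnot(min_area_px >= 1)
  m <- mask
  if (opening_radius > 0) {
    brush <- EBImage::makeBrush(2L * opening_radius + 1L, shape = "box")
    m <- EBImage::opening(mask * 1L, brush) > 0.5
  }
  lab <- label_components8(m)
  empty <- data.frame(x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0),
                      area_px = integer(0), confidence = numeric(0))
  nlab <- max(lab)
  if (nlab == 0) return(list(count = 0L, detections = empty))
  H <- nrow(m)
  idx <- which(lab > 0)
  comp <- lab[idx]
  rr <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  area <- tabulate(comp, nlab)
  keep <- which(area >= min_area_px)
  if (!length(keep)) return(list(count = 0L, detections = empty))
  x_min <- tapply(cc, comp, min)[keep] - 1L
  x_max <- tapply(cc, comp, max)[keep]
  y_min <- tapply(rr, comp, min)[keep] - 1L
  y_max <- tapply(rr, comp, max)[keep]
  a <- area[keep]
  det <- data.frame(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                    x_max = as.numeric(x_max), y_max = as.numeric(y_max),
                    area_px = as.integer(a),
                    confidence = pmin(1, a / stats::median(a)))
  det$confidence <- pmax(det$confidence, 1e-6)
  rownames(det) <- NULL
  list(count = nrow(det), detections = det)
}

#' Altitude-scaled minimum component area
#'
#' Seedling pixel area shrinks with the square of altitude, so the
#' area filter scales accordingly from a 15 m base value.
#'
#' @param base_at_15m Minimum area at 15 m (default 60 px).
#' @param altitude_m Altitude in meters.
#' @return Integer minimum area (>= 1).
#' @export
scaled_min_area <- function(base_at_15m = 60, altitude_m) {
  max(1L, as.integer(ceiling(base_at_15m * (15 / altitude_m)^2)))
}
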