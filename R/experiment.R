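#' End-to-end altitude experiment
#'
#' Orchestrates the full pipeline per flight altitude: synthetic dataset
#' generation, color-index separability analysis, SVM training on the
#' training split, counting on the validation split, and metric reporting
#' (a model x altitude results table plus per-image count comparisons).
#'
#' @name experiment
NULL

#' Build an experiment configuration
#'
#' @param out_dir Output directory for images, labels, CSVs and plots.
#' @param altitudes Flight altitudes in meters.
#' @param images_per_altitude Scenes per altitude (default 36, split 2:1).
#' @param split_ratio Train:validation ratio string.
#' @param index_name Working color index for segmentation features.
#' @param svm List of SVM options (`kernel`, `cost`, `max_train`).
#' @param min_area_base Minimum component area at 15 m; scaled by
#'   (15/altitude)^2 at other altitudes.
#' @param opening_radius Square opening radius in pixels.
#' @param n_svm_images Training images per altitude used for patch sampling.
#' @param n_patches Patches per class per training image.
#' @param patch_size_at_15m Patch side in pixels at 15 m; scales inversely
#'   with altitude so patches cover a constant ground footprint.
#' @param count_range Per-image seedling count range.
#' @param image_size Scene size `(height_px, width_px)`.
#' @param seed Root seed; every stage derives its randomness from it.
#' @param make_plots Write scatter/count plots as PNG (default TRUE).
#' @param scene Extra arguments passed to [scene_spec()] (e.g.
#'   `overlap_fraction`, `weed_density`, `noise_sd`).
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(out_dir = tempfile("seedstand_"),
                              altitudes = c(15, 30, 45),
                              images_per_altitude = 36L,
                              split_ratio = "2:1",
                              index_name = "EXG",
                              svm = list(kernel = "linear", cost = 1),
                              min_area_base = 60,
                              opening_radius = 0L,
                              n_svm_images = 8L,
                              n_patches = 12L,
                              patch_size_at_15m = 20L,
                              count_range = c(10L, 32L),
                              image_size = c(560L, 560L),
                              seed = 1L,
                              make_plots = TRUE,
                              scene = list()) {
  structure(as.list(environment()), class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file whose keys match [experiment_config()] arguments.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(experiment_config, cfg)
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(...)))
}

run_stage <- function(stage, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  log_stage(stage, sprintf("done in %.1fs",
                           as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

# Patch corners for separability analysis, derived from ground truth:
# foreground patches centered on boxes, background patches away from them.
# Background patches emulate an annotator picking visually clean soil:
# besides avoiding every labeled box they must contain no green-dominant
# pixel (soil is always red-dominant; unlabeled weeds are not).
truth_patches <- function(image, truth, patch_size, n_each = 8L, seed = 1L) {
  H <- dim(image)[1]; W <- dim(image)[2]
  pb <- yolo_to_pixel(truth$boxes, H, W)
  greenish <- image[, , 2] > image[, , 1] + 5
  with_seed(seed, {
    # several jittered candidates per box, keep the greenest (an annotator
    # centers the sample on leaf material, not on the box corner soil)
    cand <- do.call(rbind, lapply(seq_len(nrow(pb)), function(b) {
      cy <- (pb$y_min[b] + pb$y_max[b]) / 2
      cx <- (pb$x_min[b] + pb$x_max[b]) / 2
      jit <- cbind(cy + stats::rnorm(8, sd = patch_size / 4),
                   cx + stats::rnorm(8, sd = patch_size / 4))
      data.frame(row = pmax(1, pmin(H - patch_size + 1,
                                    round(jit[, 1] - patch_size / 2))),
                 col = pmax(1, pmin(W - patch_size + 1,
                                    round(jit[, 2] - patch_size / 2))))
    }))
    fill <- vapply(seq_len(nrow(cand)), function(i) {
      mean(greenish[cand$row[i]:(cand$row[i] + patch_size - 1L),
                    cand$col[i]:(cand$col[i] + patch_size - 1L)])
    }, numeric(1))
    k <- min(n_each, nrow(cand))
    fg <- cand[order(-fill)[seq_len(k)], , drop = FALSE]
    bg <- data.frame(row = numeric(0), col = numeric(0))
    att <- 0
    while (nrow(bg) < n_each && att < 4000) {
      att <- att + 1
      r0 <- sample.int(H - patch_size + 1L, 1)
      c0 <- sample.int(W - patch_size + 1L, 1)
      hit <- any(pb$x_min < c0 + patch_size & pb$x_max > c0 &
                 pb$y_min < r0 + patch_size & pb$y_max > r0)
      if (hit) next
      if (any(greenish[r0:(r0 + patch_size - 1L),
                       c0:(c0 + patch_size - 1L)])) next
      bg <- rbind(bg, data.frame(row = r0, col = c0))
    }
    if (!nrow(bg)) stop("no background patch found", call. = FALSE)
    list(fg = fg, bg = bg)
  })
}

#' Run the altitude experiment
#'
#' @param config An [experiment_config()].
#' @return List with `results` (model x altitude metric table),
#'   `counts` (per-image truth vs predicted), `separability` (per-altitude
#'   index ranking), `manifest`, and the paths of the written CSV files.
#'   The same config always reproduces byte-identical CSVs.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- run_stage("generate", {
    tmpl <- do.call(scene_spec, c(list(rng_seed = config$seed,
                                       image_size = config$image_size),
                                  config$scene))
    generate_dataset(tmpl, config$images_per_altitude,
                     altitudes = config$altitudes,
                     out_dir = file.path(config$out_dir, "images"),
                     count_range = config$count_range,
                     split_ratio = config$split_ratio)
  })

  sep_rows <- list()
  res_rows <- list()
  count_rows <- list()
  for (alt in config$altitudes) {
    sub <- manifest[manifest$altitude == alt, ]
    train <- sub[sub$split == "train", ]
    val <- sub[sub$split == "val", ]
    patch_px <- max(6L, as.integer(round(config$patch_size_at_15m * 15 / alt)))

    sep <- run_stage(sprintf("separability@%gm", alt), {
      # average the per-index scores over a few training images: a single
      # image's handful of patches gives noisy eta estimates
      n_sep <- min(4L, nrow(train))
      reps <- lapply(seq_len(n_sep), function(i) {
        img <- read_rgb(train$image[i])
        truth <- list(boxes = read_yolo_labels(train$label[i]))
        pp <- truth_patches(img, truth, patch_px, seed = config$seed + i)
        as.data.frame(separability_analysis(img, pp$fg, pp$bg,
                                            patch_size = patch_px))
      })
      pooled <- do.call(rbind, reps)
      agg <- stats::aggregate(
        pooled[, c("eta_at_optimum", "histogram_overlap")],
        by = list(index_name = pooled$index_name), FUN = mean)
      agg <- agg[order(-agg$eta_at_optimum), ]
      agg$altitude <- alt
      agg
    })
    sep_rows[[as.character(alt)]] <- sep

    model <- run_stage(sprintf("train-svm@%gm", alt), {
      n_imgs <- min(config$n_svm_images, nrow(train))
      sets <- lapply(seq_len(n_imgs), function(i) {
        build_samples(read_rgb(train$image[i]),
                      read_yolo_labels(train$label[i]),
                      n_patches = config$n_patches,
                      patch_size = patch_px,
                      rng_seed = config$seed + 100L + i,
                      feature_config = list(chromatic = TRUE,
                                            indices = config$index_name,
                                            mask_index = NULL),
                      refine_with_index = config$index_name)
      })
      samples <- list(
        features = do.call(rbind, lapply(sets, `[[`, "features")),
        labels = factor(unlist(lapply(sets, function(s) as.character(s$labels))),
                        levels = c("soil", "sorghum")),
        feature_config = sets[[1]]$feature_config
      )
      train_pixel_svm(samples, c(config$svm,
                                 list(subsample_seed = config$seed + 7L)))
    })

    alt_eval <- run_stage(sprintf("count-val@%gm", alt), {
      min_area <- scaled_min_area(config$min_area_base, alt)
      TPs <- FPs <- FNs <- 0
      pooled_p <- list(); pooled_g <- list(); offset <- 0
      Y <- X <- integer(nrow(val))
      for (i in seq_len(nrow(val))) {
        img <- read_rgb(val$image[i])
        mask <- classify_pixels(model, img)
        cc <- count_components(mask, min_area_px = min_area,
                               opening_radius = config$opening_radius)
        gt <- yolo_to_pixel(read_yolo_labels(val$label[i]),
                            nrow(img), ncol(img))
        m <- match_detections(cc$detections, gt, iou_threshold = 0.5)
        TPs <- TPs + m$TP; FPs <- FPs + m$FP; FNs <- FNs + m$FN
        Y[i] <- nrow(gt); X[i] <- cc$count
        shift <- function(b) {
          if (!"confidence" %in% names(b)) b$confidence <- rep(1, nrow(b))
          b$class_id <- rep(0L, nrow(b))
          b$x_min <- b$x_min + offset; b$x_max <- b$x_max + offset
          b[, c(box_cols, "class_id", "confidence")]
        }
        pooled_p[[i]] <- shift(cc$detections); pooled_g[[i]] <- shift(gt)
        offset <- offset + ncol(img) + 16
      }
      prf <- detection_metrics(list(TP = TPs, FP = FPs, FN = FNs))
      mAP <- map_over_classes(do.call(rbind, pooled_p),
                              do.call(rbind, pooled_g))$mAP
      cm <- count_metrics(Y, X)
      list(prf = prf, mAP = mAP, cm = cm, Y = Y, X = X)
    })

    res_rows[[as.character(alt)]] <- data.frame(
      altitude = alt, model = "SVM",
      P = alt_eval$prf["P"], R = alt_eval$prf["R"],
      mAP50 = alt_eval$mAP, F1 = alt_eval$prf["F1"],
      R2 = alt_eval$cm["R2"], RMSE = alt_eval$cm["RMSE"],
      RRMSE_pct = alt_eval$cm["RRMSE"], row.names = NULL)
    count_rows[[as.character(alt)]] <- data.frame(
      altitude = alt, image = basename(val$image),
      true_count = alt_eval$Y, predicted_count = alt_eval$X)
  }

  results <- do.call(rbind, res_rows); rownames(results) <- NULL
  counts <- do.call(rbind, count_rows); rownames(counts) <- NULL
  separability <- do.call(rbind, sep_rows); rownames(separability) <- NULL

  paths <- list(results = file.path(config$out_dir, "results.csv"),
                counts = file.path(config$out_dir, "counts.csv"),
                separability = file.path(config$out_dir, "separability.csv"))
  utils::write.csv(results, paths$results, row.names = FALSE)
  utils::write.csv(counts, paths$counts, row.names = FALSE)
  utils::write.csv(separability, paths$separability, row.names = FALSE)

  if (isTRUE(config$make_plots)) {
    run_stage("plots", {
      p1 <- ggplot2::ggplot(counts,
              ggplot2::aes(x = true_count, y = predicted_count)) +
        ggplot2::geom_abline(linetype = 2, color = "grey50") +
        ggplot2::geom_point(alpha = 0.8) +
        ggplot2::facet_wrap(~altitude, labeller = ggplot2::label_both) +
        ggplot2::labs(x = "true count", y = "predicted count",
                      title = "Validation counts by altitude")
      ggplot2::ggsave(file.path(config$out_dir, "count_scatter.png"), p1,
                      width = 9, height = 3.2, dpi = 120)
      cl <- counts
      cl$idx <- stats::ave(seq_len(nrow(cl)), cl$altitude, FUN = seq_along)
      p2 <- ggplot2::ggplot(cl, ggplot2::aes(x = idx)) +
        ggplot2::geom_line(ggplot2::aes(y = true_count,
                                        color = "true")) +
        ggplot2::geom_line(ggplot2::aes(y = predicted_count,
                                        color = "predicted")) +
        ggplot2::facet_wrap(~altitude, labeller = ggplot2::label_both) +
        ggplot2::labs(x = "validation image", y = "seedlings", color = NULL)
      ggplot2::ggsave(file.path(config$out_dir, "count_series.png"), p2,
                      width = 9, height = 3.2, dpi = 120)
      invisible(NULL)
    })
  }

  list(results = results, counts = counts, separability = separability,
       manifest = manifest, paths = paths)
}
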