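#' Synthetic UAV field imagery with exact ground truth
#'
#' Generates nadir views of row-planted green seedlings on textured brown
#' soil, emulating multi-altitude UAV capture: the ground sample distance
#' (GSD) grows linearly with altitude, so the pixel footprint of a plant
#' shrinks quadratically. Every image comes with one ground-truth bounding
#' box per seedling, which makes the full segmentation/counting pipeline
#' testable without any external imagery.
#'
#' @name synthetic_field
NULL

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Scene specification for the synthetic field generator
#'
#' @param altitude_m Flight altitude in meters (typical survey altitudes are 15,
#'   30 and 45).
#' @param image_size Integer `(height_px, width_px)`.
#' @param n_seedlings Number of seedlings (= ground-truth boxes) to place.
#' @param row_spacing_m Planting row spacing in meters (default 0.6).
#' @param overlap_fraction Fraction of seedlings deliberately placed touching
#'   a neighbor, creating the merged-canopy counting challenge.
#' @param illumination_gradient Relative amplitude of a linear brightness
#'   ramp across the image (0 = flat lighting).
#' @param noise_sd Per-pixel Gaussian sensor noise, in 0-255 channel units.
#' @param weed_density Unlabeled weeds per square meter of ground.
#' @param rng_seed Integer seed; identical specs give bit-identical scenes.
#' @param gsd_cm_per_px Ground sample distance. Defaults to 0.5 cm/px at
#'   15 m, scaling linearly with altitude (only relative scale matters).
#' @param plants_per_box Rosettes rendered per labeled hill (default 1).
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(altitude_m = 15, image_size = c(560L, 560L),
                       n_seedlings = 25L, row_spacing_m = 0.6,
                       overlap_fraction = 0.05, illumination_gradient = 0.15,
                       noise_sd = 3, weed_density = 0.5, rng_seed = 1L,
                       gsd_cm_per_px = NULL, plants_per_box = 1L) {
  if (is.null(gsd_cm_per_px)) gsd_cm_per_px <- 0.5 * altitude_m / 15
  stopifnot(altitude_m > 0, gsd_cm_per_px > 0, n_seedlings >= 0,
            row_spacing_m > 0, overlap_fraction >= 0, overlap_fraction <= 1,
            illumination_gradient >= 0, noise_sd >= 0, weed_density >= 0,
            plants_per_box >= 1)
  if (length(image_size) != 2 || any(image_size <= 0)) {
    stop("image_size must be two positive integers", call. = FALSE)
  }
  structure(list(altitude_m = altitude_m,
                 gsd_cm_per_px = gsd_cm_per_px,
                 image_size = as.integer(image_size),
                 n_seedlings = as.integer(n_seedlings),
                 row_spacing_m = row_spacing_m,
                 overlap_fraction = overlap_fraction,
                 illumination_gradient = illumination_gradient,
                 noise_sd = noise_sd,
                 weed_density = weed_density,
                 rng_seed = as.integer(rng_seed),
                 plants_per_box = as.integer(plants_per_box)),
            class = "scene_spec")
}

# Low-frequency random field: coarse iid normal grid, bilinear upsample.
smooth_noise <- function(H, W, cell_px) {
  m <- max(2L, ceiling(H / cell_px) + 1L)
  n <- max(2L, ceiling(W / cell_px) + 1L)
  C <- matrix(stats::rnorm(m * n), m, n)
  ri <- seq(1, m, length.out = H); ci <- seq(1, n, length.out = W)
  rlo <- pmin(floor(ri), m - 1L); rf <- ri - rlo
  A <- C[rlo, , drop = FALSE] * (1 - rf) + C[rlo + 1L, , drop = FALSE] * rf
  clo <- pmin(floor(ci), n - 1L); cf <- ci - clo
  sweep(A[, clo, drop = FALSE], 2, 1 - cf, `*`) +
    sweep(A[, clo + 1L, drop = FALSE], 2, cf, `*`)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Sum/mean over k x k blocks: block_mean emulates the sensor integrating
# ground detail over each pixel's footprint.
block_sum <- function(M, k) {
  if (k == 1L) return(M)
  rowagg <- function(A) matrix(colSums(matrix(A, nrow = k)), nrow = nrow(A) / k)
  t(rowagg(t(rowagg(M))))
}

block_mean <- function(M, k) block_sum(M, k) / k^2

# Soil background: brown base with low-frequency brightness and hue
# variation (yellowish clods, gray stones) plus fine speckle.
render_soil <- function(H, W, px_per_m) {
  # dry clods (yellowish), stones (gray) and red-yellow earth patches
  # (iron-rich, blue-poor) over the base brown, plus brightness and speckle
  brown  <- c(118, 92, 62)
  yellow <- c(158, 128, 88)
  gray   <- c(105, 105, 105)
  redyellow <- c(138, 90, 44)
  bright <- 1 + 0.12 * smooth_noise(H, W, round(0.30 * px_per_m) + 2L)
  wy <- clamp01(0.22 + 0.20 * smooth_noise(H, W, round(0.20 * px_per_m) + 2L))
  wg <- clamp01(0.12 + 0.15 * smooth_noise(H, W, round(0.12 * px_per_m) + 2L))
  wr <- clamp01(0.20 + 0.18 * smooth_noise(H, W, round(0.25 * px_per_m) + 2L))
  wg <- pmin(wg, 1 - wy)
  wr <- pmin(wr, 1 - wy - wg)
  wb <- 1 - wy - wg - wr
  speck <- matrix(stats::rnorm(H * W, sd = 7), H, W)
  img <- array(0, dim = c(H, W, 3))
  for (k in 1:3) {
    img[, , k] <- (wb * brown[k] + wy * yellow[k] + wg * gray[k] +
                     wr * redyellow[k]) * bright + speck
  }
  img
}

# Paint an elliptical leaf into mask/image layers. Returns linear indices.
leaf_pixels <- function(H, W, cy, cx, theta, len, wid) {
  # leaf ellipse centered len/2 from the rosette center, long axis along theta
  ecy <- cy + sin(theta) * len / 2
  ecx <- cx + cos(theta) * len / 2
  r <- ceiling(len / 2 + wid / 2) + 1L
  rows <- max(1L, floor(ecy - r)):min(H, ceiling(ecy + r))
  cols <- max(1L, floor(ecx - r)):min(W, ceiling(ecx + r))
  if (!length(rows) || !length(cols)) return(integer(0))
  dy <- rows - ecy
  dx <- cols - ecx
  u <- outer(dy, dx, function(a, b) a * sin(theta) + b * cos(theta))
  v <- outer(dy, dx, function(a, b) a * cos(theta) - b * sin(theta))
  inside <- (u / (len / 2))^2 + (v / (wid / 2))^2 <= 1
  ij <- which(inside, arr.ind = TRUE)
  if (!nrow(ij)) return(integer(0))
  (cols[ij[, 2]] - 1L) * H + rows[ij[, 1]]
}

# One rosette of 6-9 leaves; returns its mask pixel indices and color.
render_rosette <- function(H, W, cy, cx, radius_px) {
  n_leaves <- sample(6:9, 1)
  base <- stats::runif(1, 0, 2 * pi)
  px <- integer(0)
  for (j in seq_len(n_leaves)) {
    theta <- base + 2 * pi * (j - 1) / n_leaves + stats::rnorm(1, sd = 0.25)
    len <- radius_px * stats::runif(1, 0.75, 1.0) # leaf tip reaches <= radius
    wid <- 0.36 * len
    px <- c(px, leaf_pixels(H, W, cy, cx, theta, len, wid))
  }
  unique(px)
}

place_centers <- function(spec, H, W, radius_px, px_per_m) {
  n <- spec$n_seedlings
  if (n == 0) return(matrix(numeric(0), 0, 2))
  row_px <- spec$row_spacing_m * px_per_m
  n_rows <- max(1L, floor((W - 2 * radius_px) / row_px))
  x0 <- (W - (n_rows - 1) * row_px) / 2
  row_x <- x0 + (seq_len(n_rows) - 1) * row_px
  n_overlap <- round(spec$overlap_fraction * n)
  centers <- matrix(NA_real_, n, 2) # (cy, cx)
  min_sep <- 2.3 * radius_px
  margin <- radius_px + 1
  for (i in seq_len(n)) {
    placed <- FALSE
    for (att in seq_len(400L)) {
      if (i > n - n_overlap && i > 1) {
        # park next to an existing plant so canopies touch
        k <- sample.int(i - 1L, 1)
        ang <- stats::runif(1, 0, 2 * pi)
        d <- stats::runif(1, 1.0, 1.4) * radius_px
        cy <- centers[k, 1] + sin(ang) * d
        cx <- centers[k, 2] + cos(ang) * d
        ok_sep <- TRUE
      } else {
        r <- sample.int(n_rows, 1)
        cx <- row_x[r] + stats::rnorm(1, sd = 0.04 * px_per_m)
        cy <- stats::runif(1, margin, H - margin)
        ok_sep <- i == 1 ||
          min((centers[seq_len(i - 1), 1] - cy)^2 +
              (centers[seq_len(i - 1), 2] - cx)^2) >= min_sep^2
      }
      if (cy >= margin && cy <= H - margin && cx >= margin &&
          cx <= W - margin && ok_sep) {
        centers[i, ] <- c(cy, cx)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place ", n, " seedlings without overlap; ",
           "enlarge image_size or reduce n_seedlings", call. = FALSE)
    }
  }
  centers
}

#' Generate one synthetic field scene
#'
#' Renders seedlings (multi-leaf green rosettes arranged in rows), soil
#' texture, unlabeled weeds, an illumination gradient and sensor noise, and
#' returns the image together with exact ground truth. The same spec always
#' produces bit-identical output.
#'
#' @param spec A [scene_spec()].
#' @return List with `image` (H x W x 3 integer-valued array, 0-255) and
#'   `truth`, a `ground_truth` object: list with `boxes` (data frame of
#'   normalized YOLO columns `class_id`, `x_center`, `y_center`, `width`,
#'   `height`), `count`, and `mask` (logical H x W vegetation mask of the
#'   labeled plants) plus per-plant pixel areas in `areas_px`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$image_size[1]; W <- spec$image_size[2]
  # Render geometry at a fine reference GSD (0.5 cm/px) and integrate over
  # k x k blocks down to the requested GSD, as a real sensor does over each
  # pixel's ground footprint. Mixed border pixels, blur of thin leaves and
  # the merging of near-touching canopies at coarse GSD all follow from
  # this integration.
  k <- max(1L, as.integer(round(spec$gsd_cm_per_px / 0.5)))
  Hr <- H * k; Wr <- W * k
  px_per_m <- 100 / (spec$gsd_cm_per_px / k)
  radius_px <- 0.08 * px_per_m # ~16 cm canopy diameter, a month after transplant
  with_seed(spec$rng_seed, {
    img <- render_soil(Hr, Wr, px_per_m)
    centers <- place_centers(spec, Hr, Wr, radius_px, px_per_m)
    plant_px <- vector("list", spec$n_seedlings)
    plant_col <- vector("list", spec$n_seedlings)
    green <- c(75, 108, 58)
    for (i in seq_len(spec$n_seedlings)) {
      # plant-to-plant variation is mostly brightness (leaf angle, vigor);
      # hue varies only mildly
      jit <- stats::rnorm(3, sd = 2.5)
      col_i <- pmax((green + jit) * stats::runif(1, 0.8, 1.2), c(20, 50, 10))
      px <- integer(0)
      for (p in seq_len(spec$plants_per_box)) {
        off <- if (p == 1) c(0, 0) else stats::rnorm(2, sd = 0.4 * radius_px)
        px <- unique(c(px, render_rosette(
          Hr, Wr, centers[i, 1] + off[1], centers[i, 2] + off[2],
          radius_px * stats::runif(1, 0.55, 1.2))))
      }
      if (!length(px)) { # off-grid degenerate draw: force one pixel
        px <- (round(centers[i, 2]) - 1L) * Hr + round(centers[i, 1])
      }
      plant_px[[i]] <- px
      plant_col[[i]] <- col_i
    }
    # weeds: smaller, yellower, never labeled
    area_m2 <- (Hr / px_per_m) * (Wr / px_per_m)
    n_weeds <- stats::rpois(1, spec$weed_density * area_m2)
    weed_px <- vector("list", n_weeds)
    weed_col <- vector("list", n_weeds)
    for (w in seq_len(n_weeds)) {
      wy <- stats::runif(1, 2, Hr - 1); wx <- stats::runif(1, 2, Wr - 1)
      wr <- stats::runif(1, 0.015, 0.03) * px_per_m # 3-6 cm young weeds
      weed_px[[w]] <- render_rosette(Hr, Wr, wy, wx, wr)
      weed_col[[w]] <- c(96, 116, 44) + stats::rnorm(3, sd = 8)
    }
    # cast shadows: canopy silhouettes displaced along the scene's sun
    # vector, darkened and lit only by blue-rich skylight; painted before
    # the canopies so plants overwrite their own shadow
    sun <- stats::runif(1, 0, 2 * pi)
    dyx <- round(0.9 * radius_px * c(sin(sun), cos(sun)))
    shift_px <- function(px) {
      rr <- ((px - 1L) %% Hr) + 1L + dyx[1]
      cc <- ((px - 1L) %/% Hr) + 1L + dyx[2]
      ok <- rr >= 1 & rr <= Hr & cc >= 1 & cc <= Wr
      (cc[ok] - 1L) * Hr + rr[ok]
    }
    shadow <- unique(unlist(c(lapply(plant_px, shift_px),
                              lapply(weed_px, shift_px))))
    shadow <- setdiff(shadow, unlist(c(plant_px, weed_px)))
    if (length(shadow)) {
      sky <- c(0.48, 0.54, 0.66)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[shadow] <- plane[shadow] * sky[ch]
        img[, , ch] <- plane
      }
    }
    paint <- function(px, col) {
      shade <- 1 + stats::rnorm(length(px), sd = 0.08)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[px] <- col[ch] * shade
        img[, , ch] <<- plane
      }
    }
    for (w in seq_len(n_weeds)) {
      if (length(weed_px[[w]])) paint(weed_px[[w]], weed_col[[w]])
    }
    for (i in seq_len(spec$n_seedlings)) paint(plant_px[[i]], plant_col[[i]])
    if (k > 1L) {
      img <- array(vapply(1:3, function(ch) block_mean(img[, , ch], k),
                          matrix(0, H, W)), dim = c(H, W, 3))
    }
    # ground truth at target resolution: a pixel belongs to a plant when
    # that plant covers at least half of its footprint
    mask <- matrix(FALSE, H, W)
    boxes <- vector("list", spec$n_seedlings)
    areas <- integer(spec$n_seedlings)
    for (i in seq_len(spec$n_seedlings)) {
      px <- plant_px[[i]]
      rr <- ((px - 1L) %% Hr) + 1L
      cc <- ((px - 1L) %/% Hr) + 1L
      tr <- (rr - 1L) %/% k + 1L
      tc <- (cc - 1L) %/% k + 1L
      cell <- (tc - 1L) * H + tr
      cov <- table(cell)
      keep <- as.integer(names(cov)[cov >= k^2 / 2])
      if (!length(keep)) keep <- as.integer(names(cov)[which.max(cov)])
      mask[keep] <- TRUE
      areas[i] <- length(keep)
      krr <- ((keep - 1L) %% H) + 1L
      kcc <- ((keep - 1L) %/% H) + 1L
      boxes[[i]] <- c(min(kcc) - 1L, min(krr) - 1L, max(kcc), max(krr))
    }
    if (spec$illumination_gradient > 0) {
      ang <- stats::runif(1, 0, 2 * pi)
      ramp <- outer(seq(0, 1, length.out = H) * sin(ang),
                    seq(0, 1, length.out = W) * cos(ang), `+`)
      ramp <- (ramp - min(ramp)) / max(max(ramp) - min(ramp), 1e-12)
      fac <- 1 + spec$illumination_gradient * (2 * ramp - 1)
      for (ch in 1:3) img[, , ch] <- img[, , ch] * fac
    }
    # smooth warm-cool color-balance drift, as left by exposure and
    # white-balance differences between the frames blended into an
    # orthomosaic; brightness cancels in chromatic coordinates but this
    # color drift does not
    warmcool <- 0.035 * smooth_noise(H, W, max(8L, round(H / 4)))
    img[, , 1] <- img[, , 1] * (1 + warmcool)
    img[, , 3] <- img[, , 3] * (1 - warmcool)
    if (spec$noise_sd > 0) {
      img <- img + array(stats::rnorm(H * W * 3, sd = spec$noise_sd),
                         dim = c(H, W, 3))
    }
    img <- round(pmin(pmax(img, 0), 255))

    bx <- if (spec$n_seedlings > 0) do.call(rbind, boxes) else
      matrix(numeric(0), 0, 4)
    # store coordinates as parsed 6-decimal values so that label files
    # round-trip exactly
    dec6 <- function(x) as.numeric(sprintf("%.6f", x))
    boxes_df <- data.frame(
      class_id = rep(0L, nrow(bx)),
      x_center = dec6((bx[, 1] + bx[, 3]) / 2 / W),
      y_center = dec6((bx[, 2] + bx[, 4]) / 2 / H),
      width    = dec6((bx[, 3] - bx[, 1]) / W),
      height   = dec6((bx[, 4] - bx[, 2]) / H)
    )
    truth <- structure(list(boxes = boxes_df, count = spec$n_seedlings,
                            mask = mask, areas_px = areas),
                       class = "ground_truth")
    list(image = img, truth = truth)
  })
}

#' Generate a multi-altitude image dataset on disk
#'
#' Writes PNG images, YOLO-format label files and a manifest CSV for
#' `n_images_per_altitude` scenes at each requested altitude, with the
#' seedling count of each scene drawn uniformly from `count_range`. Every
#' scene covers the same ground footprint regardless of altitude — the
#' template's `image_size` is the pixel size at 15 m, and higher altitudes
#' shrink it by 15/altitude (the same plot seen with a coarser GSD, as when
#' plots are cropped out of surveys flown at several heights). Each
#' altitude stratum is split 2:1 (train:validation by default) with a
#' seeded shuffle.
#'
#' @param spec_template A [scene_spec()] providing all non-varying
#'   parameters; per-image seeds are derived from its `rng_seed`.
#' @param n_images_per_altitude Images per altitude (>= 1).
#' @param altitudes Altitudes in meters (default `c(15, 30, 45)`).
#' @param out_dir Output directory (created if missing).
#' @param count_range Inclusive integer range of seedling counts per image.
#' @param split_ratio Train:validation ratio string (default `"2:1"`).
#' @return The manifest data frame (one row per image: `image`, `label`,
#'   `altitude`, `count`, `seed`, `split`), also written to
#'   `out_dir/manifest.csv`.
#' @export
generate_dataset <- function(spec_template, n_images_per_altitude,
                             altitudes = c(15, 30, 45), out_dir,
                             count_range = c(10L, 32L),
                             split_ratio = "2:1") {
  stopifnot(inherits(spec_template, "scene_spec"),
            n_images_per_altitude >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  rows <- list()
  idx <- 0L
  for (alt in altitudes) {
    for (i in seq_len(n_images_per_altitude)) {
      idx <- idx + 1L
      seed_i <- (spec_template$rng_seed + 7919L * idx) %% .Machine$integer.max
      n_i <- with_seed(seed_i,
                       sample(count_range[1]:count_range[2], 1))
      sp <- spec_template
      sp$altitude_m <- alt
      sp$gsd_cm_per_px <- 0.5 * alt / 15
      sp$image_size <- as.integer(round(spec_template$image_size * 15 / alt))
      sp$n_seedlings <- as.integer(n_i)
      sp$rng_seed <- as.integer(seed_i)
      scene <- generate_scene(sp)
      stem <- sprintf("alt%02d_img%03d", as.integer(alt), i)
      img_path <- file.path(out_dir, paste0(stem, ".png"))
      lab_path <- file.path(out_dir, paste0(stem, ".txt"))
      write_rgb(scene$image, img_path)
      write_yolo_labels(scene$truth$boxes, lab_path)
      rows[[idx]] <- data.frame(image = img_path, label = lab_path,
                                altitude = alt, count = n_i, seed = seed_i)
    }
  }
  manifest <- do.call(rbind, rows)
  manifest <- split_dataset(manifest, ratio = split_ratio,
                            stratify_by = "altitude",
                            rng_seed = spec_template$rng_seed)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
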