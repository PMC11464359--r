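#' Maximum inter-class variance (Otsu) thresholding
#'
#' Threshold selection that maximizes the variance between the two gray-level
#' populations split at a candidate threshold t: pixels with gray value <= t
#' form class 0 (proportion omega0, mean mu0), the rest class 1 (omega1,
#' mu1). The global mean is mu = omega0*mu0 + omega1*mu1 and the inter-class
#' variance is
#'
#'   S(t) = omega0*(mu0 - mu)^2 + omega1*(mu1 - mu)^2.
#'
#' The selected threshold T maximizes S; the normalized criterion
#' eta = S(T)/total variance lies in \[0, 1\] and reaches 1 only for
#' two-valued images.
#'
#' @name otsu
NULL

#' Quantize a real-valued index image to gray levels
#'
#' Linear min-max mapping to integers 0..255 with half-up rounding.
#' Constant images map to all zeros and are flagged.
#'
#' @param index_image An `index_image` (or a bare numeric matrix).
#' @param bins Number of gray levels (default 256, i.e. values 0..255).
#' @return Object of class `gray_image`: list with integer matrix `values`,
#'   `mapping = c(min_val, max_val)` and logical `constant`.
#' @export
quantize <- function(index_image, bins = 256L) {
  v <- if (inherits(index_image, "index_image")) index_image$values else index_image
  if (!is.matrix(v)) stop("expected a matrix of index values", call. = FALSE)
  if (any(!is.finite(v))) stop("index image contains NaN/Inf pixels", call. = FALSE)
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    g <- matrix(0L, nrow(v), ncol(v))
    constant <- TRUE
  } else {
    g <- matrix(as.integer(floor((v - lo) / (hi - lo) * (bins - 1L) + 0.5)),
                nrow(v), ncol(v))
    constant <- FALSE
  }
  structure(list(values = g, mapping = c(min_val = lo, max_val = hi),
                 constant = constant),
            class = "gray_image")
}

# Per-threshold class statistics from a 256-bin count vector.
# Returns a list of length-256 vectors indexed by t = 0..255 (class 0: <= t).
# Class means divide the (exact) cumulative sums by the (exact) cumulative
# counts, so results agree bit-for-bit with a direct per-threshold
# evaluation.
otsu_curves <- function(counts, levels = seq_along(counts) - 1) {
  n <- sum(counts)
  n0 <- cumsum(counts)
  n1 <- n - n0
  w0 <- n0 / n
  w1 <- n1 / n
  csum <- cumsum(counts * levels)
  total <- csum[length(csum)]
  mu <- total / n
  mu0 <- ifelse(n0 > 0, csum / n0, 0)
  mu1 <- ifelse(n1 > 0, (total - csum) / n1, 0)
  S <- w0 * (mu0 - mu)^2 + w1 * (mu1 - mu)^2
  list(w0 = w0, w1 = w1, mu0 = mu0, mu1 = mu1, mu = mu, S = S)
}

#' Otsu threshold of a gray image
#'
#' Scans every candidate threshold t in 0..255, computes the class
#' proportions, class means and inter-class variance S(t), and returns the
#' smallest t maximizing S. When the image has zero total variance the
#' result is flagged `degenerate` with T = 0.
#'
#' @param gray A `gray_image` from [quantize()], an integer matrix with
#'   values in 0..255, or a length-256 histogram of counts.
#' @return Object of class `otsu_result`: list with integer threshold `T`,
#'   class proportions `omega0`/`omega1`, class means `mu0`/`mu1`, global
#'   mean `mu`, inter-class variance `S`, normalized criterion `eta`, and
#'   logical `degenerate`.
#' @examples
#' g <- matrix(c(rep(10L, 5), rep(200L, 5)), 2)
#' otsu_threshold(g)$T # 10
#' @export
otsu_threshold <- function(gray) {
  counts <- gray_counts(gray)
  if (sum(counts) == 0) stop("empty image", call. = FALSE)
  cv <- otsu_curves(counts)
  total_var <- sum(counts * ((seq_along(counts) - 1) - cv$mu)^2) / sum(counts)
  if (total_var == 0) {
    return(structure(list(T = 0L, omega0 = 1, omega1 = 0, mu0 = cv$mu,
                          mu1 = 0, mu = cv$mu, S = 0, eta = 0,
                          degenerate = TRUE),
                     class = "otsu_result"))
  }
  Tt <- which.max(cv$S) # ties: smallest t (which.max takes the first)
  structure(list(T = as.integer(Tt - 1L), omega0 = cv$w0[Tt],
                 omega1 = cv$w1[Tt], mu0 = cv$mu0[Tt], mu1 = cv$mu1[Tt],
                 mu = cv$mu, S = cv$S[Tt], eta = cv$S[Tt] / total_var,
                 degenerate = FALSE),
            class = "otsu_result")
}

# A gray_image or matrix is treated as pixels; a bare numeric vector of
# length 256 as a histogram of counts over gray levels 0..255.
gray_counts <- function(gray) {
  if (inherits(gray, "gray_image")) gray <- gray$values
  if (is.matrix(gray)) {
    if (length(gray) == 0) stop("empty image", call. = FALSE)
    return(tabulate(as.integer(gray) + 1L, nbins = 256L))
  }
  if (is.numeric(gray) && length(gray) == 256L) return(as.numeric(gray))
  if (is.numeric(gray) && length(gray) > 0) {
    return(tabulate(as.integer(gray) + 1L, nbins = 256L))
  }
  stop("unsupported gray input", call. = FALSE)
}

#' Segment an index image into a vegetation mask
#'
#' Quantizes the index image, finds the Otsu threshold, and orients the
#' binary mask so that TRUE = vegetation according to the index's
#' vegetation polarity (high tail for greenness indices, low tail for
#' excess red). Degenerate (zero-contrast) images yield an all-background
#' mask.
#'
#' @param index_image An `index_image` from [compute_index()] or
#'   [rgb_to_index()].
#' @return Logical H x W matrix with attributes `otsu` (the `otsu_result`)
#'   and `degenerate`.
#' @export
segment <- function(index_image) {
  if (!inherits(index_image, "index_image")) {
    stop("`index_image` must come from compute_index()", call. = FALSE)
  }
  g <- quantize(index_image)
  res <- otsu_threshold(g)
  if (res$degenerate || g$constant) {
    mask <- matrix(FALSE, nrow(g$values), ncol(g$values))
  } else if (index_image$vegetation_polarity == "high") {
    mask <- g$values > res$T
  } else {
    mask <- g$values <= res$T
  }
  attr(mask, "otsu") <- res
  attr(mask, "degenerate") <- res$degenerate || g$constant
  mask
}

#' Foreground/background separability of the eight color indices
#'
#' Quantifies, per color index, how well vegetation and soil pixel samples
#' separate: 20 x 20 pixel patches of each class are transformed by each
#' index, pooled and quantized to 256 gray levels, and scored by (a) Otsu's
#' normalized criterion eta on the pooled pixels and (b) the overlap of the
#' normalized class histograms, sum(min(fg_bin, bg_bin)) in \[0, 1\]
#' (0 = disjoint, 1 = identical).
#'
#' @param image H x W x 3 RGB array.
#' @param fg_patches,bg_patches Matrices (or data frames) with columns
#'   `row`, `col`: top-left corners (1-based) of vegetation and soil
#'   patches.
#' @param patch_size Patch side length in pixels (default 20).
#' @return Object of class `separability_report`: a data frame with one row
#'   per index (`index_name`, `eta_at_optimum`, `histogram_overlap`),
#'   sorted by decreasing eta, with the per-index normalized histograms in
#'   attribute `histograms`.
#' @export
separability_analysis <- function(image, fg_patches, bg_patches,
                                  patch_size = 20L) {
  assert_rgb(image)
  fg_patches <- as.matrix(as.data.frame(fg_patches)[, c("row", "col")])
  bg_patches <- as.matrix(as.data.frame(bg_patches)[, c("row", "col")])
  if (nrow(fg_patches) < 1 || nrow(bg_patches) < 1) {
    stop("need at least one patch of each class", call. = FALSE)
  }
  H <- dim(image)[1]; W <- dim(image)[2]
  check_bounds <- function(p) {
    if (any(p[, 1] < 1 | p[, 2] < 1 |
            p[, 1] + patch_size - 1 > H | p[, 2] + patch_size - 1 > W)) {
      stop("patch outside image bounds", call. = FALSE)
    }
  }
  check_bounds(fg_patches); check_bounds(bg_patches)

  patch_idx <- function(patches) {
    idx <- lapply(seq_len(nrow(patches)), function(i) {
      rows <- patches[i, 1] + seq_len(patch_size) - 1L
      cols <- patches[i, 2] + seq_len(patch_size) - 1L
      as.vector(outer(rows, (cols - 1L) * H, `+`))
    })
    unlist(idx)
  }
  fg_i <- patch_idx(fg_patches); bg_i <- patch_idx(bg_patches)

  ch <- to_chromatic(image)
  rows <- lapply(index_names(), function(nm) {
    v <- compute_index(ch, original = image, name = nm)$values
    fg <- v[fg_i]; bg <- v[bg_i]
    pooled <- quantize(matrix(c(fg, bg), nrow = 1))
    q <- pooled$values[1, ]
    qf <- q[seq_along(fg)]; qb <- q[length(fg) + seq_along(bg)]
    hf <- tabulate(qf + 1L, 256L) / length(qf)
    hb <- tabulate(qb + 1L, 256L) / length(qb)
    res <- otsu_threshold(matrix(q, nrow = 1))
    list(row = data.frame(index_name = nm, eta_at_optimum = res$eta,
                          histogram_overlap = sum(pmin(hf, hb))),
         hist = list(fg = hf, bg = hb))
  })
  report <- do.call(rbind, lapply(rows, `[[`, "row"))
  hists <- lapply(rows, `[[`, "hist")
  names(hists) <- index_names()
  ord <- order(-report$eta_at_optimum)
  report <- report[ord, , drop = FALSE]
  rownames(report) <- NULL
  structure(report, histograms = hists,
            class = c("separability_report", "data.frame"))
}
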