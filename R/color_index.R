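#' Color vegetation indices
#'
#' Eight single-channel color indices commonly used to separate green
#' vegetation from soil in RGB imagery. All except the HSV saturation
#' component are functions of the chromatic coordinates r, g, b (each
#' channel's share of R+G+B), which makes them invariant to uniform
#' brightness scaling.
#'
#' @name color_index
NULL

#' Names of the supported color indices
#'
#' @return Character vector of the eight index names.
#' @export
index_names <- function() {
  c("EXG", "Cg", "EXG_EXR", "EXR", "GBDI", "NGBDI", "NGRDI", "S")
}

#' Vegetation polarity of a color index
#'
#' Which tail of the index distribution corresponds to plants: `"high"` for
#' greenness-type indices, `"low"` for the excess-red index (vegetation is
#' red-poor).
#'
#' @param name Index name, one of [index_names()].
#' @return `"high"` or `"low"`.
#' @export
vegetation_polarity <- function(name) {
  name <- match.arg(name, index_names())
  if (name == "EXR") "low" else "high"
}

assert_rgb <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("expected an H x W x 3 RGB array", call. = FALSE)
  }
  invisible(image)
}

#' Convert an RGB image to chromatic coordinates
#'
#' Maps each pixel to its channel shares r = R/(R+G+B), g = G/(R+G+B),
#' b = B/(R+G+B). Black pixels (zero channel sum) carry no color evidence;
#' they are mapped to r = g = b = 0 and flagged in `zero_sum`.
#'
#' @param image H x W x 3 numeric array with channels in \[0, 255\].
#' @return Object of class `chromatic_image`: a list with H x W matrices
#'   `r`, `g`, `b` and a logical matrix `zero_sum`.
#' @examples
#' img <- array(c(50, 100, 50), dim = c(1, 1, 3))
#' ch <- to_chromatic(img)
#' c(ch$r, ch$g, ch$b) # 0.25 0.50 0.25
#' @export
to_chromatic <- function(image) {
  assert_rgb(image)
  H <- dim(image)[1]
  R <- matrix(image[, , 1], H); G <- matrix(image[, , 2], H)
  B <- matrix(image[, , 3], H)
  s <- R + G + B
  zero <- s == 0
  s[zero] <- 1 # avoid 0/0; flagged pixels are forced to 0 below
  out <- list(r = R / s, g = G / s, b = B / s, zero_sum = zero)
  out$r[zero] <- 0; out$g[zero] <- 0; out$b[zero] <- 0
  structure(out, class = "chromatic_image")
}

#' HSV saturation of an RGB image
#'
#' S = 1 - min(R,G,B)/max(R,G,B), the saturation channel of the standard
#' hexcone HSV transform; 0 for achromatic (including black) pixels.
#'
#' @param image H x W x 3 numeric array, channels in \[0, 255\].
#' @return H x W matrix in \[0, 1\].
#' @export
hsv_saturation <- function(image) {
  assert_rgb(image)
  H <- dim(image)[1]
  mx <- matrix(pmax(image[, , 1], image[, , 2], image[, , 3]), H)
  mn <- matrix(pmin(image[, , 1], image[, , 2], image[, , 3]), H)
  ifelse(mx > 0, 1 - mn / mx, 0)
}

#' Compute one color index over an image
#'
#' Applies one of the eight supported index formulas pixelwise:
#' \describe{
#'   \item{EXG}{2g - r - b (excess green)}
#'   \item{Cg}{0.4g - 0.3r - 0.1b (YCrCb green difference)}
#'   \item{EXG_EXR}{3g - 2.4r - b (excess green minus excess red)}
#'   \item{EXR}{1.4r - g (excess red; vegetation is the low tail)}
#'   \item{GBDI}{g - b}
#'   \item{NGBDI}{(g - b)/(g + b)}
#'   \item{NGRDI}{(g - r)/(g + r)}
#'   \item{S}{HSV saturation of the original RGB}
#' }
#' Flagged zero-sum (black) pixels yield 0 for every index, as do the
#' normalized differences when their denominator is 0.
#'
#' @param chromatic A `chromatic_image` from [to_chromatic()].
#' @param original The original RGB array; required only for `"S"`.
#' @param name Index name, one of [index_names()].
#' @return Object of class `index_image`: list with the H x W `values`
#'   matrix, `index_name` and `vegetation_polarity`.
#' @export
compute_index <- function(chromatic, original = NULL, name) {
  if (!inherits(chromatic, "chromatic_image")) {
    stop("`chromatic` must come from to_chromatic()", call. = FALSE)
  }
  name <- match.arg(name, index_names())
  r <- chromatic$r; g <- chromatic$g; b <- chromatic$b
  values <- switch(name,
    EXG     = 2 * g - r - b,
    Cg      = 0.4 * g - 0.3 * r - 0.1 * b,
    EXG_EXR = 3 * g - 2.4 * r - b,
    EXR     = 1.4 * r - g,
    GBDI    = g - b,
    NGBDI   = safe_ratio(g - b, g + b),
    NGRDI   = safe_ratio(g - r, g + r),
    S = {
      if (is.null(original)) stop("the S index needs the original RGB image", call. = FALSE)
      hsv_saturation(original)
    }
  )
  values[chromatic$zero_sum] <- 0
  structure(
    list(values = values, index_name = name,
         vegetation_polarity = vegetation_polarity(name)),
    class = "index_image"
  )
}

safe_ratio <- function(num, den) {
  out <- num / den
  out[den == 0] <- 0
  out
}

#' One-call index image from RGB
#'
#' Convenience wrapper: [to_chromatic()] then [compute_index()].
#'
#' @inheritParams to_chromatic
#' @param name Index name.
#' @return An `index_image`.
#' @export
rgb_to_index <- function(image, name) {
  compute_index(to_chromatic(image), original = image, name = name)
}
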