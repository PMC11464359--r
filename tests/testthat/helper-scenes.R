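# Shared scene fixtures, built once per test run.

.scene_cache <- new.env(parent = emptyenv())

cached_scene <- function(altitude_m = 15, n_seedlings = 20L, rng_seed = 3L,
                         ...) {
  key <- paste(altitude_m, n_seedlings, rng_seed,
               paste(deparse(list(...)), collapse = ""), sep = "|")
  if (is.null(.scene_cache[[key]])) {
    size <- as.integer(round(560 * 15 / altitude_m))
    .scene_cache[[key]] <- generate_scene(scene_spec(
      altitude_m = altitude_m, n_seedlings = n_seedlings,
      rng_seed = rng_seed, image_size = c(size, size), ...))
  }
  .scene_cache[[key]]
}

# Two-tone vegetation/soil index image used in segmentation tests: blobs of
# a high index value over a uniform low background.
two_tone_index <- function(H = 60, W = 60, fg_value = 0.5, bg_value = -0.1,
                           name = "EXG") {
  v <- matrix(bg_value, H, W)
  blob <- matrix(FALSE, H, W)
  blob[10:18, 12:20] <- TRUE
  blob[35:45, 30:42] <- TRUE
  v[blob] <- fg_value
  structure(list(values = v, index_name = name,
                 vegetation_polarity = vegetation_polarity(name)),
            class = "index_image")
}
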