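test_that("patch sampling yields the expected row counts and is seeded", {
  sc <- cached_scene(rng_seed = 3)
  s1 <- build_samples(sc$image, sc$truth, n_patches = 1, patch_size = 20,
                      rng_seed = 5)
  expect_identical(nrow(s1$features), 2L * 400L)
  expect_identical(as.vector(table(s1$labels)), c(400L, 400L))
  s2 <- build_samples(sc$image, sc$truth, n_patches = 1, patch_size = 20,
                      rng_seed = 5)
  expect_identical(s1$features, s2$features)
  empty <- generate_scene(scene_spec(n_seedlings = 0, image_size = c(64, 64),
                                     rng_seed = 1))
  expect_error(build_samples(empty$image, empty$truth), "sorghum")
})

test_that("linearly separable samples train to perfect accuracy, permuted labels to chance", {
  set.seed(31)
  X <- rbind(matrix(rnorm(400, 0, 0.5), ncol = 4),
             matrix(rnorm(400, 4, 0.5), ncol = 4))
  colnames(X) <- c("r", "g", "b", "EXG")
  labels <- factor(rep(c("soil", "sorghum"), each = 100),
                   levels = c("soil", "sorghum"))
  samples <- list(features = X, labels = labels)
  fit <- train_pixel_svm(samples)
  expect_equal(training_accuracy(fit, samples), 1.0)
  # label permutation destroys the signal: accuracy near chance
  perm <- samples
  accs <- replicate(5, {
    perm$labels <- sample(labels)
    training_accuracy(train_pixel_svm(perm), perm)
  })
  expect_lt(mean(accs), 0.72)
  expect_gt(mean(accs), 0.40)
  one <- list(features = X[1:100, ], labels = labels[1:100])
  expect_error(train_pixel_svm(one), "both classes")
})

test_that("duplicating the sample set leaves the decision boundary unchanged", {
  set.seed(32)
  X <- rbind(matrix(rnorm(200, 0, 0.4), ncol = 2),
             matrix(rnorm(200, 3, 0.4), ncol = 2))
  colnames(X) <- c("f1", "f2")
  labels <- factor(rep(c("soil", "sorghum"), each = 100),
                   levels = c("soil", "sorghum"))
  f1 <- train_pixel_svm(list(features = X, labels = labels))
  f2 <- train_pixel_svm(list(features = rbind(X, X),
                             labels = c(labels, labels)))
  probe <- matrix(runif(400, -1, 4), ncol = 2,
                  dimnames = list(NULL, c("f1", "f2")))
  expect_identical(seedstand:::predict_pixels(f1, probe),
                   seedstand:::predict_pixels(f2, probe))
})

test_that("the linear fast path agrees with the reference predict method", {
  sc <- cached_scene(rng_seed = 3)
  samp <- build_samples(sc$image, sc$truth, n_patches = 10, patch_size = 20,
                        rng_seed = 5, refine_with_index = "EXG")
  fit <- train_pixel_svm(samp)
  X <- samp$features[seq(1, nrow(samp$features), by = 3), , drop = FALSE]
  fast <- seedstand:::predict_pixels(fit, X)
  slow <- as.character(predict(fit$fit, X)) == "sorghum"
  expect_identical(fast, slow)
})

test_that("pixel classification recovers the vegetation mask of the training scene", {
  sc <- cached_scene(rng_seed = 3)
  samp <- build_samples(sc$image, sc$truth, n_patches = 15, patch_size = 20,
                        rng_seed = 5, refine_with_index = "EXG")
  model <- train_pixel_svm(samp)
  mask <- classify_pixels(model, sc$image)
  tv <- sc$truth$mask
  expect_gt(sum(mask & tv) / sum(mask | tv), 0.7)
  # an all-soil image classifies almost entirely as background
  soil <- generate_scene(scene_spec(n_seedlings = 0, image_size = c(128, 128),
                                    weed_density = 0, rng_seed = 8))
  expect_lt(mean(classify_pixels(model, soil$image)), 0.05)
  # deterministic
  expect_identical(mask, classify_pixels(model, sc$image))
  bad <- model
  bad$feature_names <- c(bad$feature_names, "extra")
  expect_error(classify_pixels(bad, sc$image), "dimension")
})

test_that("component counting, area filtering and opening behave on constructed masks", {
  m <- matrix(FALSE, 20, 30)
  m[3:7, 3:7] <- TRUE
  m[10:14, 20:24] <- TRUE
  cc <- count_components(m, min_area_px = 4, opening_radius = 0)
  expect_identical(cc$count, 2L)
  expect_identical(cc$count, nrow(cc$detections))
  expect_identical(cc$detections$area_px, c(25L, 25L))
  expect_true(all(cc$detections$confidence == 1))
  # boxes are half-open pixel rectangles within image bounds
  d <- cc$detections[1, ]
  expect_identical(c(d$x_min, d$y_min, d$x_max, d$y_max), c(2, 2, 7, 7))
  expect_identical(count_components(m, min_area_px = 26)$count, 0L)
  # a one-pixel bridge joins the squares; opening radius 1 removes it
  m2 <- matrix(FALSE, 20, 30)
  m2[3:7, 3:7] <- TRUE
  m2[3:7, 12:16] <- TRUE
  m2[5, 8:11] <- TRUE
  expect_identical(count_components(m2, min_area_px = 4,
                                    opening_radius = 0)$count, 1L)
  expect_identical(count_components(m2, min_area_px = 4,
                                    opening_radius = 1)$count, 2L)
  expect_error(count_components(m * 1L), "logical")
})

test_that("labeling is 8-connected and min_area is monotone in the count", {
  m <- matrix(FALSE, 10, 10)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE # touch only diagonally
  expect_identical(count_components(m, min_area_px = 1,
                                    opening_radius = 0)$count, 1L)
  set.seed(33)
  rm <- matrix(runif(40 * 40) < 0.3, 40, 40)
  counts <- vapply(1:12, function(a) {
    count_components(rm, min_area_px = a, opening_radius = 0)$count
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("minimum component area scales with the inverse square of altitude", {
  expect_identical(scaled_min_area(60, 15), 60L)
  expect_identical(scaled_min_area(60, 30), 15L)
  expect_identical(scaled_min_area(60, 45), 7L) # ceiling(60/9)
  expect_identical(scaled_min_area(2, 90), 1L)  # floor of 1
})
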