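test_that("quantize maps linearly to 0..255 with half-up rounding", {
  q <- quantize(matrix(c(0, 2), 1))
  expect_identical(as.vector(q$values), c(0L, 255L))
  expect_false(q$constant)
  q3 <- quantize(matrix(c(0, 1, 2), 1))
  expect_identical(as.vector(q3$values), c(0L, 128L, 255L)) # 127.5 rounds up
  qc <- quantize(matrix(0.7, 3, 3))
  expect_true(qc$constant)
  expect_true(all(qc$values == 0L))
  expect_error(quantize(matrix(c(1, NaN), 1)), "NaN")
})

test_that("two-level image reproduces the hand-derived class statistics", {
  g <- matrix(c(rep(10L, 5), rep(200L, 5)), nrow = 2)
  res <- otsu_threshold(g)
  expect_identical(res$T, 10L)
  expect_equal(res$omega0, 0.5)
  expect_equal(res$omega1, 0.5)
  expect_equal(res$mu0, 10)
  expect_equal(res$mu1, 200)
  expect_equal(res$mu, 105)
  expect_equal(res$S, 9025) # total variance 95^2, fully between-class
  expect_equal(res$eta, 1)
  expect_false(res$degenerate)
})

test_that("constant image is degenerate with zero inter-class variance", {
  res <- otsu_threshold(matrix(42L, 4, 4))
  expect_true(res$degenerate)
  expect_identical(res$T, 0L)
  expect_equal(res$S, 0)
  expect_error(otsu_threshold(matrix(integer(0), 0, 0)), "empty")
})

test_that("threshold and S match the naive double-loop oracle on random histograms", {
  set.seed(21)
  for (rep in 1:300) {
    counts <- switch(1 + rep %% 3,
      rpois(256, 4),
      {h <- numeric(256); h[sample(256, 12)] <- sample(1:50, 12, TRUE); h},
      round(500 * (dnorm(0:255, 70, 15) + dnorm(0:255, 180, 25))))
    if (sum(counts) == 0) counts[1] <- 1
    got <- otsu_threshold(counts)
    want <- otsu_oracle(counts)
    if (got$degenerate) {
      expect_equal(max(want$curve), 0)
    } else {
      expect_identical(got$T, want$T)
      expect_equal(got$S, want$S, tolerance = 1e-12)
    }
  }
})

test_that("variance decomposes into between- plus within-class at every threshold", {
  set.seed(22)
  for (rep in 1:20) {
    g <- matrix(sample(0:255, 400, replace = TRUE, prob = runif(256)), 20)
    counts <- tabulate(g + 1L, 256L)
    n <- sum(counts)
    lv <- 0:255
    mu <- sum(lv * counts) / n
    total_var <- sum(counts * (lv - mu)^2) / n
    cv <- seedstand:::otsu_curves(counts)
    # Eq-style conservation at every candidate threshold
    expect_equal(cv$w0 + cv$w1, rep(1, 256), tolerance = 1e-12)
    expect_equal(cv$w0 * cv$mu0 + cv$w1 * cv$mu1, rep(mu, 256),
                 tolerance = 1e-9)
    # S(t) + within-class variance(t) == total variance for all t
    within <- vapply(0:255, function(t) {
      lo <- counts[seq_len(t + 1)]; hi <- counts[(t + 2):256]
      v0 <- if (sum(lo) > 0) sum(lo * (lv[seq_len(t + 1)] - cv$mu0[t + 1])^2) / n else 0
      v1 <- if (t < 255 && sum(hi) > 0) sum(hi * (lv[(t + 2):256] - cv$mu1[t + 1])^2) / n else 0
      v0 + v1
    }, numeric(1))
    expect_equal(cv$S + within, rep(total_var, 256), tolerance = 1e-9)
  }
})

test_that("adding a constant gray offset shifts the threshold by that offset", {
  set.seed(23)
  g <- matrix(sample(0:200, 300, replace = TRUE), 15)
  t0 <- otsu_threshold(g)$T
  for (k in c(5L, 30L, 55L)) {
    expect_identical(otsu_threshold(g + k)$T, t0 + k)
  }
})

test_that("segment orients the mask by vegetation polarity and handles flats", {
  iv <- two_tone_index(fg_value = 0.5, bg_value = -0.1, name = "EXG")
  mask <- segment(iv)
  expect_identical(mask[, ], iv$values > 0)
  # same scene through an excess-red lens: vegetation is the LOW tail
  ir <- two_tone_index(fg_value = -0.2, bg_value = 0.25, name = "EXR")
  mask2 <- segment(ir)
  expect_identical(mask2[, ], ir$values < 0)
  expect_identical(unname(which(mask)), unname(which(mask2)))
  # all-soil: degenerate, all background
  flat <- two_tone_index(fg_value = -0.1, bg_value = -0.1)
  m3 <- segment(flat)
  expect_true(attr(m3, "degenerate"))
  expect_false(any(m3))
})

test_that("separability scores the no-signal and two-point extremes correctly", {
  set.seed(24)
  # fg and bg drawn from one distribution: overlap near 1, eta small
  img <- array(sample(60:200, 40 * 40 * 3, replace = TRUE), dim = c(40, 40, 3))
  same <- separability_analysis(img,
                                fg_patches = data.frame(row = 1, col = 1),
                                bg_patches = data.frame(row = 21, col = 21),
                                patch_size = 20)
  expect_true(all(same$histogram_overlap > 0.5))
  # constant-valued classes at two gray levels: overlap 0, eta 1
  img2 <- array(0, dim = c(40, 40, 3))
  img2[1:20, 1:20, 1] <- 60;  img2[1:20, 1:20, 2] <- 180; img2[1:20, 1:20, 3] <- 60
  img2[21:40, 21:40, 1] <- 150; img2[21:40, 21:40, 2] <- 100; img2[21:40, 21:40, 3] <- 50
  two <- separability_analysis(img2,
                               fg_patches = data.frame(row = 1, col = 1),
                               bg_patches = data.frame(row = 21, col = 21),
                               patch_size = 20)
  for (nm in setdiff(index_names(), "S")) {
    row <- two[two$index_name == nm, ]
    expect_equal(row$histogram_overlap, 0, info = nm)
    expect_equal(row$eta_at_optimum, 1, tolerance = 1e-9, info = nm)
  }
  expect_error(
    separability_analysis(img, data.frame(row = 30, col = 30),
                          data.frame(row = 1, col = 1), patch_size = 20),
    "bounds")
})
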